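---
title: "Methods: exposure windows, epigenetic gestational age, and distributed lag models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure windows, epigenetic gestational age, and distributed lag models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gestwin)
```

This vignette documents the models `gestwin` implements, the assumptions
behind them, the design choices that were genuinely open, and what the
synthetic-data validation does and does not establish about real cohorts.

## The scientific setting

Prenatal ambient air pollution is an established risk factor for adverse
birth outcomes, and placental DNA methylation is one proposed mechanism.
Epigenetic gestational age (EGA) — gestational age predicted from placental
methylation by a trained linear clock — summarizes the tissue's biological
maturity; its residual against chronologic gestational age (CGA) defines
gestational age acceleration (positive) or deceleration (negative),
GAA/GAD. The analytic question is whether pollutant exposure in specific
pregnancy weeks shifts GAA/GAD at birth, i.e. whether there are *critical
exposure windows*.

Because cohorts of this kind are small (about a hundred pregnancies) and
the underlying data are typically not public, `gestwin` pairs the analysis
chain with a generator that emulates the full data-generating process and
records the ground truth, so the chain's operating characteristics can be
measured instead of assumed.

## Exposure assignment

Weekly station concentrations are interpolated to a residence by inverse
distance-squared weighting. Station eligibility follows a two-ring rule:
if any station lies within 5 km, only stations within 5 km are used;
otherwise up to the 4 nearest stations within 50 km; with none, the week is
missing. Distances are haversine on a sphere of radius 6371.0088 km — at
network scales (< 50 km) the spherical error is negligible. Distances below
1 m are floored so a collocated station dominates the weights without
dividing by zero. Ties in distance are broken by station id so results are
order-independent.

The weekly axis unifies preconception and pregnancy: weeks 1–13 are the 13
complete 7-day weeks before conception ("3 months", and the only split
consistent with a 48-week axis ending at pregnancy week 35), week 14 is
pregnancy week 1. A participant week is matched to the station week
containing its midpoint day.

Period averages are arithmetic means of non-missing weekly values,
reported only when the period's missing fraction is at most 10% (strictly
more than 10% missing yields a missing average). Trimesters are defined by
pregnancy days 1–90, 91–180, and 181–birth; with weekly data the
majority-day rule assigns pregnancy weeks 1–13, 14–26, and 27–birth (the
straddling weeks 13 and 26 have most of their days inside trimesters 1 and
2 respectively).

## Synthetic cohorts and the truth record

The generator's defaults describe the emulated study conditions: 103
pregnancies; chronologic GA truncated-normal with mean 39.2 and SD 1.4
weeks on [28, 42], with 8% of the mass below 37 weeks (the approximate
preterm share implied by a full-term sensitivity subset of 95 of 103);
conception dates uniform over one calendar year so birth seasons are
balanced; four pollutants (NO2, O3, PM2.5, PM10) with baselines matching
the cohort's reported period averages (13, 26, 10, 17.5), seasonal sine
components, a smooth spatial gradient, and week-to-week noise split into a
regional AR(1) component shared across space (70% of the variance) and
station-local white noise — so nearby stations are informative about a
residence, and interpolation error is realistically nonzero. Ground-truth
exposure at a residence is the same latent field evaluated at the residence
coordinates (with its own local-noise realization), never the interpolated
value, so assignment error can be quantified separately from model error.

Biological GA is planted as
`bioGA = CGA + gamma * (mean windowed exposure)/10 + N(0, 1.2)` with the
window defaulting to unified weeks 34–44 (pregnancy weeks 21–31) and
`gamma = -0.7` weeks per 10 units — the magnitude class of the
period-average estimates such cohorts report. The individual noise SD of
1.2 weeks was chosen once so that the correlation between EGA and CGA on
default cohorts falls in the 0.5–0.9 band around the observed r = 0.63 of
the emulated design; measured values are about 0.7–0.77.

Methylation is generated per CpG role. Clock CpGs follow
`logit(beta) = a_j + b_j (bioGA - 39.2) + batch + noise` with slopes
`|b_j|` of 0.05–0.12 logit units per week — the logit link keeps beta in
(0,1) by construction. A `link = "linear"` mode generates beta exactly
linear in bioGA for clean clock round-trip fixtures; under the logit link
the recorded truth clock is the linearization at the GA centre and is
flagged approximate. Background CpGs carry no GA signal. A 600-CpG
reference panel with six placental cell types (syncytiotrophoblast,
trophoblasts, Hofbauer, endothelial, stromal, nucleated red blood cells)
mixes with Dirichlet-distributed true proportions centred on the reported
cohort composition (64.5% syncytiotrophoblast, concentration 63 chosen to
match the reported spreads). Sex-chromosome CpGs separate males (low
methylation) from females (intermediate, reflecting X-inactivation).
Plate batch effects act on the logit scale with per-feature heterogeneity
around the plate mean — the structure parametric empirical Bayes
adjustment assumes. Detection p-values fail i.i.d. at a configurable rate,
and the generator plants configurable numbers of low-intensity,
sex-discordant and twin samples for the QC stage to find.

Two seeds control the generator. The master `seed` drives sampling
(stations, participants, noise, batches) through fixed per-component
stream offsets, so changing the number of participants never perturbs the
station series. A separate `biology_seed` (defaulting to `seed`) drives
feature-level biology — clock CpG intercepts and slopes, background
levels, the reference panel — so that independent cohorts can share one
biological universe. This matters whenever a clock trained on one cohort
is applied to another, as `run_pipeline()` does.

Reduced-form generators (`simulate_association_cohort()`,
`simulate_dlm_cohort()`) draw period averages or weekly exposure matrices
and outcomes directly from the regression-level model, skipping the
methylation layer; they exist because calibration studies need thousands
of fitted cohorts. The DLM benchmark plants its effect as a raised-cosine
lag profile peaked at the window centre, giving a well-defined peak week
for recovery scoring; the cohort-level generator keeps the flat windowed
mean that defines its truth record. The benchmark's planted effect of
−2 weeks per 10 units was chosen a priori as a clearly detectable signal
for a recovery/power benchmark at n = 150; at the −0.7 magnitude class and
n ≈ 100, single cohorts are underpowered, which is itself a documented
operating characteristic (see the power-monotonicity test).

## Methylation quality control

The QC order is fixed and mirrors standard array practice: probe filters →
sample filters → twin deduplication → batch adjustment → gold-standard
normalization → PC outlier flagging.

Probes are dropped when detection p exceeds 0.01 in strictly more than 10%
of samples, or when listed cross-reactive (the list is an input file, not a
bundled database, because such annotations are versioned externally).
Samples are dropped for >10% failing probes, median log2 intensity strictly
below 11 relative fluorescence units, missing reported sex, or discordance
between reported sex and sex predicted by two-means clustering of mean
beta over X-chromosome probes (the lower-mean cluster is male; degenerate
clustering ties break toward keeping the sample). One twin per family is
retained by seeded random selection.

Batch adjustment is ComBat-style parametric empirical Bayes, applied on
the logit (M-value-like) scale with a 1e-6 clipping offset, because the
location/scale model assumes approximately Gaussian data and beta values
are neither Gaussian nor unbounded. Feature-wise batch locations are
shrunk toward their across-feature mean under a normal prior and batch
scales toward a pooled inverse-gamma prior, estimated by the standard
iterative moment equations. Two deliberate contract choices: a single
batch is returned unchanged, and after adjustment every feature is
recentred to its original grand mean on the logit scale — batch
adjustment should reallocate variation between batches, not move
feature-level means. A test cross-checks the implementation against
`sva::ComBat` on a shared fixture (correlation of adjusted matrices
> 0.999, identical batch-gap shrinkage within 5%).

Gold-standard normalization implements the rescaling contract of
beta-mixture quantile dilation without its probe-type mixture model: each
sample is mapped through the rank-preserving quantile map onto a reference
distribution (by default the per-probe means of the retained samples).
Plotting positions `(rank-1)/(n-1)` with type-7 quantiles make a sample
already distributed as the reference an exact fixed point. The full
probe-type model was not implemented because only the rescaling behaviour
is contracted; this is the one place the pipeline deliberately simplifies
the emulated study's method.

Visual PC inspection is replaced by a deterministic rule: samples whose
first two principal components lie more than k = 3 robust SDs (MAD ×
1.4826) from their sex group's median in either component are flagged.
Reproducibility demands a deterministic surrogate for "visually
inspected". The k-MAD rule's false-flag rate is governed by Gaussian tails
inflated by the sampling noise of the MAD itself — about 1–2 false flags
per 100 homogeneous samples at k = 3 — so k is exposed as a parameter and
`k = Inf` disables the step.

## Cell-type deconvolution

Constrained projection: per sample, minimize `||b - Rw||^2` subject to
`w >= 0` and `sum(w) <= 1`, solved exactly as a quadratic program
(`quadprog`). The inequality (rather than equality) sum constraint is the
cited formulation's, and reported compositions in this field sum near but
not exactly to 100%; weights are therefore reported unnormalized with
their sum, and `renormalize = TRUE` rescales to the simplex for use as
regression covariates — both paths are exposed because published analyses
are silent on which was used. Missing CpGs are dropped pairwise per
sample, with at least 80% of the panel required and a rank check after
dropping.

## Clocks and age-acceleration residuals

`predict_ega()` is deliberately strict: every clock CpG must be present
(no imputation), mirroring the emulated study's "no required CpG sites
were missing". `train_clock()` fits an elastic net (default mixing 0.5)
with seeded 10-fold cross-validation for the penalty, returning only
nonzero-coefficient CpGs; it exists to train clocks on synthetic cohorts,
since published placental clock coefficients are external to this
package's scope.

Intrinsic GAA/GAD is the residual of EGA on CGA plus cell proportions;
extrinsic omits the proportions. When proportions are renormalized to sum
to one, including all six produces exact collinearity with the intercept,
so the largest compartment (syncytiotrophoblast) is dropped by default;
the dropped type is configurable because the emulated design does not
state how the simplex constraint was handled. Residuals are OLS with
intercept, hence sum to zero by construction and are orthogonal to every
included regressor — both asserted against closed-form normal-equations
oracles at 1e-10.

## Association models

Individual analytic models are OLS of the residual outcome on one period
average plus the fixed covariate roster (maternal age; race, ethnicity,
education, income, BMI category, child sex, birth season, study site, all
dummy-coded against fixed, logged reference levels), restricted to
complete cases. Effects are reported per 10 concentration units by
post-fit scaling (identical to pre-scaling the regressor), with
normal-theory t intervals — plain linear regression is the stated method
of the emulated design, so no robust/sandwich errors by default. Raw
two-sided p-values are reported with no multiple-testing adjustment across
the grid, again mirroring the design. Mutually adjusted models enter all
period averages of one pollutant simultaneously; periods correlated above
0.99 in the analysis sample are rejected as non-identifiable.

Calibration (measured by `scripts/acceptance.R` and the acceptance tests):
under a null effect the type-I error at α = 0.05 is within 0.05 ± 0.02
over 1000 simulated cohorts of n = 100; under a planted −0.7 weeks per 10
units the mean estimate is within ±0.1 and 95% CI coverage within
[0.93, 0.97] over 500 cohorts. With preconception and pregnancy averages
correlated at −0.9 and a pregnancy-only effect, the individual
preconception model is biased away from zero (omitted-variable bias,
about +0.6) while the mutually adjusted interval covers zero in ≥ 90% of
cohorts — the attenuation phenomenon such designs report.

## Distributed lag models

The weekly effect curve over the 48-lag axis is constrained to a
low-dimensional basis: polynomials of degree 0–6 in the centred and scaled
lag index (centring/scaling before powering conditions the design matrix;
the basis is stored so effects are always reported on the raw weekly
scale), or a constant column plus a natural cubic spline with boundary
knots at lags 1 and 48 and internal knots at equally spaced quantiles
(2–8 df total). The axis ends at pregnancy week 35 *structurally*:
pregnancy weeks 36–39 are excluded so preterm births do not create
missingness at the end of the lag axis. Participants with any missing week
among lags 1–48 are dropped (and counted) rather than imputed — imputation
would contaminate the lag structure. The basis order is selected by
minimum AIC (`n log(RSS/n) + 2(p+1)`; the RSS form ranks identically to
the likelihood form under Gaussian OLS), with exact ties resolved toward
the smaller order; default polynomial candidates are degrees 1–4 and
spline candidates 3–5 df.

Pointwise (per-week) t intervals, not simultaneous bands, define critical
windows — maximal runs of weeks whose interval excludes zero, each
annotated with sign and peak week — because week-range reporting in this
literature is pointwise. Consequences measured in the tests: under a null,
average per-week coverage is about 94–96%, but the probability that *some*
week somewhere excludes zero is non-trivial, so isolated one-week runs
deserve skepticism; under the benchmark's planted windows (pregnancy weeks
21–31, n = 150), a negative run overlapping the true window is found in
essentially all cohorts and the detected peak is within a median of 1 week
of the planted peak.

Two exact reductions pin the implementation: a degree-0 basis reproduces
the OLS slope on the 48-week exposure sum, identically for every lag; and
an identity basis on orthonormalized exposures reproduces the 48
independent per-week OLS slopes. `θ = Bη` is definitional and asserted
bit-exact.

## Problem sizes and numerical choices

The validation suite simulates at the scales the inference requires, not
larger: 1000 cohorts (n = 100) for type-I error, 500 for recovery and
coverage, 200 for mutual adjustment and window recovery, 200 six-type
mixtures for deconvolution, and a 5000-CpG, 400-sample cohort (300
training / 100 held out, 558 informative CpGs) for the clock benchmark —
the full suite runs in a few minutes on one CPU. Logit transforms clip at
1e-6; the empirical Bayes iteration stops at relative change 1e-4; QP
solutions are exact to solver tolerance and floored at zero; OLS uses QR
with rank checks that name offending columns.

## Limitations

The generator emulates structure, not realism: CpGs are exchangeable
within roles (no genomic annotation, no probe-type chemistry, no
correlated CpG blocks), pollutant fields are stationary sinusoid-plus-AR(1)
(no episodic pollution events), covariates carry only small planted
effects (no structured confounding between exposure and covariates), and
residential mobility is absent. Passing tests therefore demonstrate that
the chain recovers what it is pointed at under its stated assumptions —
correct interpolation, calibrated inference, window recovery at detectable
effect sizes — not that any particular real-cohort finding is correct.
The raw-intensity stages of array processing (background subtraction, dye
normalization, probe-type correction) are upstream of this pipeline, which
starts at beta values, detection p-values and per-sample intensity
summaries.
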