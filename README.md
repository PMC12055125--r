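# gestwin

Critical windows of prenatal ambient air pollution exposure for placental
epigenetic gestational age at birth.

## What this package is for

Epidemiologic studies of prenatal air pollution increasingly use
DNA-methylation-based *epigenetic gestational age* (EGA) as a biomarker of
the newborn's biological maturity. The analysis chain behind such a study
is long: weekly pollutant concentrations from monitoring stations must be
interpolated to each maternal residence, placental 450k-style methylation
data must pass quality control and batch adjustment, cell-type composition
must be estimated and adjusted for, a linear clock converts methylation
into EGA, and regression models relate exposure averages — or the full
weekly exposure history — to gestational age acceleration/deceleration
(GAA/GAD) at birth.

`gestwin` implements that whole chain as tested, reusable R functions, plus
a synthetic-cohort generator with a complete ground-truth record so every
stage can be validated against known answers. It is aimed at environmental
epidemiologists and biostatisticians who want to study the operating
characteristics of this design (power, calibration, window recovery) or to
run the same models on their own cohort files.

## The models at the core

**Exposure assignment.** Weekly station values are interpolated to a
residence by inverse distance-squared weighting,
`x = Σ(v_i/d_i²) / Σ(1/d_i²)`, using all stations within 5 km if any exist,
otherwise up to the 4 nearest stations within 50 km. Exposures live on a
unified weekly axis: weeks 1–13 are preconception, week 14 is pregnancy
week 1. Period averages (preconception, pregnancy, trimesters 1–3) are
arithmetic means of weekly values, reported only when at most 10% of the
period's weeks are missing.

**Age acceleration.** EGA is a linear clock over clock-CpG beta values,
`EGA_i = a + Σ_j w_j β_ij`. Extrinsic GAA/GAD is the residual of
`EGA ~ CGA` (chronologic gestational age); intrinsic GAA/GAD additionally
adjusts for estimated cell-type proportions. Positive residuals mean
accelerated biological aging, negative decelerated.

**Association models.** For each pollutant, period and outcome, OLS of the
residual on the period average plus the covariate roster (maternal age,
race, ethnicity, education, income, BMI category, child sex, birth season,
study site), reported per 10-unit increment with t-based 95% CIs.
Mutually adjusted models enter all periods of one pollutant simultaneously.

**Distributed lag models.** The weekly effect curve `θ_l` over lags
1–48 is constrained to a polynomial or natural-cubic-spline basis,
`θ = B η`, fitted by OLS of the outcome on `[covariates | X B]`; the basis
order is chosen by AIC. Critical windows are maximal runs of weeks whose
pointwise 95% CI excludes zero.

## Worked example

```r
library(gestwin)
res <- run_pipeline(simulation_config(seed = 1))

# the cohort after QC, with epigenetic and chronologic GA
head(res$age_accel, 3)
#>   sample_id ega_weeks cga_weeks intrinsic_gaa extrinsic_gaa
#> 1      p001  39.86566      39.6     0.2412747     0.3936607
#> 2      p002  40.42512      40.6     0.4667224     0.4589799
#> 3      p003  40.31422      41.2    -0.1703931     0.0515985

cor(res$age_accel$ega_weeks, res$age_accel$cga_weeks)
#> [1] 0.7402042

# pregnancy-average ozone association, weeks of GA change per 10 ppb
subset(res$assoc_grid, pollutant == "O3" & period == "pregnancy",
       c(outcome, n, beta_per_10, ci_low, ci_high, p))
#>      outcome  n beta_per_10    ci_low   ci_high         p
#> 12 intrinsic 93  -0.3554940 -1.549198 0.8382105 0.5546617
#> 17 extrinsic 93  -0.3842745 -1.618361 0.8498125 0.5368043
```

The default configuration simulates 103 pregnancies with a planted ozone
effect of −0.7 weeks of biological GA per 10 ppb confined to pregnancy
weeks 21–31. At that cohort size a single run is underpowered — exactly the
regime such cohorts operate in — so the package's validation rests on the
Monte-Carlo calibration studies in `tests/testthat/test-acceptance.R`
(type-I error, CI coverage, window recovery at detectable effect sizes).

The numbered scripts under `analysis/` run the same chain step by step,
writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1     # cohort + truth record
Rscript analysis/02_assign_exposures.R      # IDW weekly + period averages
Rscript analysis/03_methylation_qc.R 1      # QC, batch adjust, normalize
Rscript analysis/04_deconvolution.R         # cell-type proportions
Rscript analysis/05_clock.R 1               # clock training + GAA/GAD
Rscript analysis/06_associations.R          # period-average models
Rscript analysis/07_distributed_lag.R       # weekly DLMs + windows
```

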