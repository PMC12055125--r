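# Methylation QC: probe and sample filters at their strict thresholds,
# twin deduplication, empirical Bayes batch adjustment, gold-standard
# quantile normalization, and the PC-based outlier flag.

make_detp <- function(fail_counts, n_samples) {
  G <- length(fail_counts)
  m <- matrix(0.001, G, n_samples,
              dimnames = list(sprintf("cg%03d", seq_len(G)),
                              sprintf("s%03d", seq_len(n_samples))))
  for (g in seq_len(G)) if (fail_counts[g] > 0)
    m[g, seq_len(fail_counts[g])] <- 0.5
  m
}

test_that("probe filter applies the strict >10% detection rule and the cross-reactive list", {
  detp <- make_detp(c(11, 10, 0, 0), 100)
  out <- filter_probes(detp)
  expect_identical(out$dropped$id, "cg001")          # 11% fails, strict
  expect_true("cg002" %in% out$retained)             # exactly 10% retained

  out2 <- filter_probes(detp, cross_reactive_ids = "cg003")
  expect_identical(out2$dropped$reason[out2$dropped$id == "cg003"],
                   "cross_reactive")

  clean <- filter_probes(make_detp(c(0, 0, 0), 50))
  expect_identical(nrow(clean$dropped), 0L)
  expect_error(filter_probes(matrix(numeric(0), 0, 0)), "empty")

  # idempotence: re-filtering the retained set drops nothing
  again <- filter_probes(detp[out$retained, , drop = FALSE])
  expect_identical(nrow(again$dropped), 0L)
})

test_that("sample filter applies intensity, detection, and sex-concordance rules", {
  set.seed(3)
  n <- 12
  ids <- sprintf("s%03d", 1:n)
  G <- 60
  x_ids <- sprintf("cgx%02d", 1:10)
  sex <- rep(c("male", "female"), each = n / 2)
  beta <- matrix(runif(G * n, 0.3, 0.7), G, n,
                 dimnames = list(c(sprintf("cg%03d", 1:(G - 10)), x_ids),
                                 ids))
  beta[x_ids, sex == "male"] <- runif(10 * sum(sex == "male"), 0.10, 0.20)
  beta[x_ids, sex == "female"] <- runif(10 * sum(sex == "female"), 0.40, 0.55)
  detp <- matrix(0.001, G, n, dimnames = dimnames(beta))
  detp[1:30, 1] <- 0.5                       # 50% failing probes for s001
  inten <- data.frame(sample_id = ids,
                      median_log2_intensity = c(12, 10.9, 11.0,
                                                rep(12.5, n - 3)))
  reported <- sex
  reported[4] <- "female"                    # male profile reported female
  reported[5] <- NA                          # missing reported sex
  sheet <- data.frame(sample_id = ids, reported_sex = reported)

  out <- filter_samples(detp, inten, sheet, beta, x_ids)
  d <- setNames(out$dropped$reason, out$dropped$id)
  expect_identical(d[["s001"]], "detection")
  expect_identical(d[["s002"]], "low_intensity")   # 10.9 < 11, strict
  expect_true("s003" %in% out$retained)            # exactly 11.0 retained
  expect_identical(d[["s004"]], "sex_discordant")
  expect_identical(d[["s005"]], "sex_missing")

  # idempotence on the retained subset
  keep <- out$retained
  again <- filter_samples(detp[, keep], inten[inten$sample_id %in% keep, ],
                          sheet[sheet$sample_id %in% keep, ],
                          beta[, keep], x_ids)
  expect_identical(nrow(again$dropped), 0L)
})

test_that("twin deduplication keeps exactly one twin, chosen by seeded RNG", {
  sheet <- data.frame(sample_id = c("a", "b", "c"),
                      family_id = c("f1", "f1", "f2"))
  out <- dedup_twins(sheet, seed = 5)
  expect_identical(nrow(out$dropped), 1L)
  expect_true(out$dropped$id %in% c("a", "b"))
  expect_identical(out$dropped$reason, "twin_dedup")
  expect_true("c" %in% out$retained)
  expect_identical(dedup_twins(sheet, seed = 5), out)   # seeded determinism
})

test_that("batch adjustment removes planted shifts, preserves protected effects and grand means", {
  set.seed(12)
  G <- 1000; n <- 60
  sex <- rep(c("male", "female"), each = n / 2)
  batch <- rep(c(1, 2), times = n / 2)
  beta <- matrix(runif(G, 0.2, 0.8), G, n) +
    matrix(rnorm(G * n, 0, 0.02), G, n)
  beta[1:300, ] <- beta[1:300, ] +
    rep(0.04 * (sex == "female"), each = 300)        # protected sex effect
  shift_rows <- 501:1000                             # planted 0.05 batch shift
  beta[shift_rows, batch == 2] <- beta[shift_rows, batch == 2] + 0.05
  beta <- pmin(pmax(beta, 0.001), 0.999)
  dimnames(beta) <- list(sprintf("cg%04d", 1:G), sprintf("s%02d", 1:n))

  adj <- eb_batch_adjust(beta, batch, data.frame(sex = sex))
  gap <- function(m) rowMeans(m[shift_rows, batch == 2]) -
    rowMeans(m[shift_rows, batch == 1])
  expect_gte(1 - mean(abs(gap(adj))) / mean(abs(gap(beta))), 0.90)

  sex_gap <- function(m) mean(rowMeans(m[1:300, sex == "female"]) -
                                rowMeans(m[1:300, sex == "male"]))
  expect_lt(abs(sex_gap(adj) - sex_gap(beta)) / abs(sex_gap(beta)), 0.05)

  # per-feature grand means on the logit scale are preserved
  lo <- function(p) log(pmin(pmax(p, 1e-6), 1 - 1e-6) /
                          (1 - pmin(pmax(p, 1e-6), 1 - 1e-6)))
  expect_lt(max(abs(rowMeans(lo(adj)) - rowMeans(lo(beta)))), 1e-6)

  # a single batch is returned unchanged
  one <- eb_batch_adjust(beta, rep(1, n), data.frame(sex = sex))
  expect_lt(max(abs(lo(one) - lo(beta))), 1e-8)

  expect_error(eb_batch_adjust(beta, c(rep(1, n - 1), 9)), "9")
})

test_that("batch adjustment agrees with an independent ComBat implementation", {
  skip_if_not_installed("sva")
  set.seed(19)
  G <- 400; n <- 40
  sex <- rep(c("male", "female"), each = n / 2)
  batch <- rep(c(1, 2), times = n / 2)
  beta <- matrix(runif(G, 0.3, 0.7), G, n) + matrix(rnorm(G * n, 0, 0.03), G, n)
  beta[, batch == 2] <- beta[, batch == 2] + 0.03
  beta <- pmin(pmax(beta, 0.01), 0.99)
  dimnames(beta) <- list(sprintf("cg%03d", 1:G), sprintf("s%02d", 1:n))
  lo <- function(p) log(p / (1 - p))

  ours <- log(eb_batch_adjust(beta, batch, data.frame(sex = sex)) /
                (1 - eb_batch_adjust(beta, batch, data.frame(sex = sex))))
  theirs <- suppressMessages(
    sva::ComBat(lo(beta), batch = batch,
                mod = stats::model.matrix(~ sex)))
  expect_gt(stats::cor(as.vector(ours), as.vector(theirs)), 0.999)
  gap <- function(m) mean(abs(rowMeans(m[, batch == 2]) -
                                rowMeans(m[, batch == 1])))
  # both implementations shrink the batch gap, and by the same amount
  expect_lt(gap(ours), gap(lo(beta)))
  expect_lt(abs(gap(ours) - gap(theirs)) / gap(theirs), 0.05)
})

test_that("gold-standard normalization is a rank-preserving quantile map", {
  set.seed(7)
  ref <- sort(runif(200))
  x <- sample(ref)                        # same distribution as reference
  m <- matrix(x, ncol = 1, dimnames = list(NULL, "s1"))
  expect_equal(as.vector(normalize_to_gold_standard(m, ref)), x)

  y <- runif(200)
  out <- normalize_to_gold_standard(matrix(y, ncol = 1), ref)
  expect_equal(sort(out), stats::quantile(ref, (seq_len(200) - 1) / 199,
                                          type = 7, names = FALSE))

  # two samples with identical ranks normalize identically
  z1 <- runif(150)
  z2 <- qbeta(pnorm(qnorm(rank(z1) / 151)), 2, 5)[rank(z1)]
  z2 <- sort(runif(150))[rank(z1)]        # monotone distortion, same ranks
  both <- normalize_to_gold_standard(cbind(a = z1, b = z2), ref)
  expect_equal(unname(both[, "a"]), unname(both[, "b"]))

  na_in <- matrix(c(0.1, NA, 0.9, 0.4), ncol = 1)
  expect_true(is.na(normalize_to_gold_standard(na_in, ref)[2, 1]))
  expect_error(normalize_to_gold_standard(m, ref[1:5]), "too short")
})

test_that("PC outlier flag catches planted outliers and respects k", {
  set.seed(9)
  G <- 300; n <- 100
  sex <- rep(c("male", "female"), each = n / 2)
  # false flags in homogeneous cohorts follow the Gaussian tail: 2 PC tests
  # per sample at |z| > 3 give ~0.5 expected flags, inflated a few-fold by
  # the sampling noise of the per-group MAD threshold itself
  counts <- replicate(20, {
    hom <- matrix(runif(G, 0.3, 0.7), G, n) +
      matrix(rnorm(G * n, 0, 0.02), G, n)
    dimnames(hom) <- list(sprintf("cg%03d", 1:G), sprintf("s%03d", 1:n))
    length(pc_outlier_flag(hom, sex))
  })
  expect_lt(mean(counts), 0.03 * n)

  beta <- matrix(runif(G, 0.3, 0.7), G, n) + matrix(rnorm(G * n, 0, 0.02), G, n)
  dimnames(beta) <- list(sprintf("cg%03d", 1:G), sprintf("s%03d", 1:n))
  beta_out <- beta
  rows <- 1:60                            # 20% of probes shifted by 0.3
  beta_out[rows, 5] <- pmin(beta_out[rows, 5] + 0.3, 1)
  expect_true("s005" %in% pc_outlier_flag(beta_out, sex))
  expect_identical(pc_outlier_flag(beta_out, sex, k = Inf), character(0))
  expect_error(pc_outlier_flag(matrix(0.5, 10, 20),
                               rep(c("male", "female"), 10)), "degenerate")
})

test_that("the full QC pipeline removes exactly the planted problem samples", {
  cfg <- simulation_config(n_participants = 50, n_low_intensity = 2,
                           n_sex_discordant = 2, n_twin_pairs = 2, seed = 33)
  co <- simulate_cohort(cfg)
  qc <- run_methqc(co$beta, co$detection_p, co$intensity, co$samplesheet,
                   x_probe_ids = grep("^cg_sexchr_", rownames(co$beta),
                                      value = TRUE),
                   seed = 33)
  d <- qc$report$dropped_samples
  expect_setequal(d$id[d$reason == "low_intensity"],
                  co$truth$planted_qc$low_intensity)
  expect_setequal(d$id[d$reason == "sex_discordant"],
                  co$truth$planted_qc$sex_discordant)
  # one twin dropped per family still intact after the sample filters
  survivors <- setdiff(co$samplesheet$sample_id,
                       d$id[d$reason %in% c("detection", "low_intensity",
                                            "sex_missing", "sex_discordant")])
  fams <- co$samplesheet$family_id[co$samplesheet$sample_id %in% survivors]
  expect_identical(sum(d$reason == "twin_dedup"),
                   sum(table(fams) > 1))
  expect_true(all(qc$beta >= 0 & qc$beta <= 1))
})
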