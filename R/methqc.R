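# Methylation-array quality control: probe and sample filters, twin
# deduplication, ComBat-style empirical Bayes batch adjustment on the logit
# scale, gold-standard quantile normalization, and an automated PC-based
# outlier flag replacing visual inspection. Pipeline order is fixed:
# probe filters -> sample filters -> twin dedup -> batch adjustment ->
# gold-standard normalization -> PC outlier flag.

#' Filter probes by detection failure and cross-reactivity
#'
#' A probe is dropped when its detection p-value exceeds `p_thresh` in
#' strictly more than `frac_thresh` of samples, or when it appears on the
#' cross-reactive list. Detection takes precedence as the recorded reason.
#'
#' @param detection_p CpG x sample matrix of detection p-values.
#' @param cross_reactive_ids character vector of probe ids to drop.
#' @param p_thresh detection p-value threshold (default 0.01).
#' @param frac_thresh failing-sample fraction threshold (default 0.10,
#'   strict inequality).
#' @return list: `retained` (probe ids), `dropped` (data frame `id`,
#'   `reason`).
#' @export
filter_probes <- function(detection_p, cross_reactive_ids = character(0),
                          p_thresh = 0.01, frac_thresh = 0.10) {
  if (is.null(dim(detection_p)) || nrow(detection_p) == 0L ||
      ncol(detection_p) == 0L)
    stop("empty detection p-value matrix")
  fail_frac <- rowMeans(detection_p > p_thresh)
  by_det <- fail_frac > frac_thresh
  by_xr <- rownames(detection_p) %in% cross_reactive_ids & !by_det
  dropped <- data.frame(
    id = c(rownames(detection_p)[by_det], rownames(detection_p)[by_xr]),
    reason = c(rep("detection", sum(by_det)),
               rep("cross_reactive", sum(by_xr))),
    stringsAsFactors = FALSE
  )
  list(retained = rownames(detection_p)[!(by_det | by_xr)],
       dropped = dropped)
}

#' Predict sample sex from X-chromosome methylation
#'
#' Two-means clustering of per-sample mean beta over the supplied
#' X-chromosome probes; the lower-mean cluster is labelled male
#' (X-inactivation raises intermediate methylation in females). With no
#' separation between clusters every sample keeps its reported label
#' upstream (ties break toward no drop).
#'
#' @param beta CpG x sample beta matrix.
#' @param x_probe_ids X-chromosome probe ids present in `beta`.
#' @return named character vector of predicted sexes, or `NA` when the
#'   clustering is degenerate.
#' @export
predict_sex <- function(beta, x_probe_ids) {
  x_probe_ids <- intersect(x_probe_ids, rownames(beta))
  stopifnot(length(x_probe_ids) > 0)
  m <- colMeans(beta[x_probe_ids, , drop = FALSE], na.rm = TRUE)
  if (diff(range(m)) < 1e-8)
    return(stats::setNames(rep(NA_character_, length(m)), names(m)))
  km <- stats::kmeans(m, centers = sort(range(m)))
  male_cluster <- which.min(km$centers)
  stats::setNames(ifelse(km$cluster == male_cluster, "male", "female"),
                  names(m))
}

#' Filter samples by detection failure, intensity, and sex concordance
#'
#' Drops samples with strictly more than `frac_thresh` of probes failing
#' detection, with median log2 intensity strictly below `intensity_thresh`
#' relative fluorescence units, with missing reported sex, or with
#' methylation-predicted sex discordant from the reported sex. Reasons are
#' recorded in that precedence order.
#'
#' @param detection_p CpG x sample detection p-value matrix.
#' @param intensity data frame `sample_id`, `median_log2_intensity`.
#' @param samplesheet data frame with `sample_id` and `reported_sex`.
#' @param beta CpG x sample beta matrix (for sex prediction).
#' @param x_probe_ids X-chromosome probe ids.
#' @param p_thresh,frac_thresh detection thresholds as in [filter_probes()].
#' @param intensity_thresh minimum acceptable median log2 intensity.
#' @return list: `retained` (sample ids), `dropped` (data frame `id`,
#'   `reason` in `{detection, low_intensity, sex_missing, sex_discordant}`).
#' @export
filter_samples <- function(detection_p, intensity, samplesheet, beta,
                           x_probe_ids, p_thresh = 0.01, frac_thresh = 0.10,
                           intensity_thresh = 11) {
  ids <- colnames(detection_p)
  fail_frac <- colMeans(detection_p > p_thresh)
  inten <- intensity$median_log2_intensity[match(ids, intensity$sample_id)]
  reported <- samplesheet$reported_sex[match(ids, samplesheet$sample_id)]
  predicted <- predict_sex(beta, x_probe_ids)[ids]

  reason <- rep(NA_character_, length(ids))
  reason[is.na(reason) & fail_frac > frac_thresh] <- "detection"
  reason[is.na(reason) & inten < intensity_thresh] <- "low_intensity"
  reason[is.na(reason) & (is.na(reported) | reported == "")] <- "sex_missing"
  discord <- !is.na(predicted) & !is.na(reported) & predicted != reported
  reason[is.na(reason) & discord] <- "sex_discordant"

  list(retained = ids[is.na(reason)],
       dropped = data.frame(id = ids[!is.na(reason)],
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE))
}

#' Randomly keep one sample per twin pair
#'
#' Among samples sharing a `family_id`, one is retained by seeded random
#' selection and the rest are dropped with reason `twin_dedup`.
#'
#' @param samplesheet data frame with `sample_id` and `family_id`.
#' @param seed RNG seed for the selection.
#' @return list: `retained`, `dropped` as in [filter_samples()].
#' @export
dedup_twins <- function(samplesheet, seed = 1) {
  set.seed(gw_stream_seed(seed, "qc"))
  keep <- character(0)
  drop <- character(0)
  for (fam in unique(samplesheet$family_id)) {
    members <- samplesheet$sample_id[samplesheet$family_id == fam]
    if (length(members) == 1L) {
      keep <- c(keep, members)
    } else {
      chosen <- sample(members, 1L)
      keep <- c(keep, chosen)
      drop <- c(drop, setdiff(members, chosen))
    }
  }
  list(retained = keep,
       dropped = data.frame(id = drop,
                            reason = rep("twin_dedup", length(drop)),
                            stringsAsFactors = FALSE))
}

# Parametric empirical Bayes iteration for one batch: shrink feature-wise
# batch locations toward their grand mean (normal prior) and scales toward
# a pooled inverse-gamma prior, as in the standard ComBat algorithm.
gw_eb_iterate <- function(z, gamma_hat, delta_hat, gbar, t2, a, b,
                          conv = 1e-4, max_iter = 200L) {
  nb <- ncol(z)
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (it in seq_len(max_iter)) {
    gamma_new <- (nb * t2 * gamma_hat + delta_star * gbar) /
      (nb * t2 + delta_star)
    ss <- rowSums((z - gamma_new)^2)
    delta_new <- (0.5 * ss + b) / (nb / 2 + a - 1)
    change <- max(abs(gamma_new - gamma_star) /
                    pmax(abs(gamma_star), 1e-8),
                  abs(delta_new - delta_star) / pmax(delta_star, 1e-8))
    gamma_star <- gamma_new
    delta_star <- delta_new
    if (change < conv) break
  }
  list(gamma = gamma_star, delta = delta_star)
}

#' Empirical Bayes batch adjustment of beta values
#'
#' ComBat-style parametric empirical Bayes on the logit (M-value like)
#' scale: a per-feature location/scale model with covariates is fitted,
#' feature-wise batch locations are shrunk toward their across-feature mean
#' (normal prior) and batch scales toward a pooled inverse-gamma prior, and
#' the shrunken batch effects are removed. After adjustment each feature is
#' recentred to its original grand mean on the logit scale, so batch
#' adjustment never moves feature-level means. A single batch is returned
#' unchanged.
#'
#' @param beta CpG x sample beta matrix, no missing entries.
#' @param batch batch label per sample (plate), length `ncol(beta)`.
#' @param covariates optional data frame of biological covariates to
#'   protect (e.g. sex), one row per sample.
#' @param eps logit clipping offset.
#' @return adjusted beta matrix on \[0,1\], same dimnames.
#' @export
eb_batch_adjust <- function(beta, batch, covariates = NULL, eps = 1e-6) {
  if (anyNA(beta)) stop("beta matrix must be complete for batch adjustment")
  batch <- factor(batch)
  if (nlevels(batch) == 1L) return(beta)
  sizes <- table(batch)
  if (any(sizes < 2))
    stop("batch with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))

  Y <- gw_logit(beta, eps)                 # G x n
  n <- ncol(Y)
  batchmod <- stats::model.matrix(~ batch - 1)
  design <- batchmod
  if (!is.null(covariates)) {
    X <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                    drop = FALSE]
    if (ncol(X) > 0) design <- cbind(batchmod, X)
  }
  if (qr(design)$rank < ncol(design))
    stop("covariates confounded with batch: design not full rank")

  nbatch <- ncol(batchmod)
  B_hat <- solve(crossprod(design), crossprod(design, t(Y)))  # p x G
  grand <- crossprod(as.numeric(sizes) / n,
                     B_hat[seq_len(nbatch), , drop = FALSE])  # 1 x G
  stand_mean <- matrix(grand, nrow(Y), n)                     # G x n
  if (ncol(design) > nbatch) {
    covpart <- design[, -seq_len(nbatch), drop = FALSE] %*%
      B_hat[-seq_len(nbatch), , drop = FALSE]                 # n x G
    stand_mean <- stand_mean + t(covpart)
  }
  resid <- Y - t(design %*% B_hat)
  var_pooled <- rowMeans(resid^2)
  var_pooled[var_pooled < 1e-12] <- 1e-12
  Z <- (Y - stand_mean) / sqrt(var_pooled)

  Z_adj <- Z
  for (b_lev in levels(batch)) {
    cols <- which(batch == b_lev)
    zb <- Z[, cols, drop = FALSE]
    gamma_hat <- rowMeans(zb)
    delta_hat <- apply(zb, 1, stats::var)
    delta_hat[delta_hat < 1e-12] <- 1e-12
    gbar <- mean(gamma_hat)
    t2 <- stats::var(gamma_hat)
    m <- mean(delta_hat); s2 <- stats::var(delta_hat)
    a <- (2 * s2 + m^2) / s2
    b_pr <- (m * s2 + m^3) / s2
    eb <- gw_eb_iterate(zb, gamma_hat, delta_hat, gbar, t2, a, b_pr)
    Z_adj[, cols] <- (zb - eb$gamma) / sqrt(eb$delta)
  }
  Y_adj <- Z_adj * sqrt(var_pooled) + stand_mean
  # batch adjustment must not move feature-level grand means
  Y_adj <- Y_adj - rowMeans(Y_adj) + rowMeans(Y)
  out <- gw_expit(Y_adj)
  dimnames(out) <- dimnames(beta)
  out
}

#' Normalize each sample to a gold-standard reference distribution
#'
#' Rank-preserving quantile mapping: each sample's values are replaced by
#' the reference quantile function evaluated at the sample's plotting
#' positions `(rank - 1) / (n - 1)`. A sample already distributed exactly as
#' the reference (same size) is a fixed point. Missing values pass through.
#'
#' @param beta CpG x sample beta matrix.
#' @param reference numeric vector defining the reference distribution
#'   (e.g. the per-probe means of a gold-standard array), at least 10
#'   values.
#' @return normalized matrix, same dimnames.
#' @export
normalize_to_gold_standard <- function(beta, reference) {
  reference <- sort(reference[!is.na(reference)])
  if (length(reference) < 10) stop("reference distribution too short (< 10)")
  out <- beta
  for (j in seq_len(ncol(beta))) {
    x <- beta[, j]
    ok <- !is.na(x)
    nx <- sum(ok)
    if (nx == 0L) next
    r <- rank(x[ok], ties.method = "average")
    p <- if (nx == 1L) 0.5 else (r - 1) / (nx - 1)
    out[ok, j] <- stats::quantile(reference, probs = p, type = 7,
                                  names = FALSE)
  }
  out
}

#' Flag principal-component outliers within sex groups
#'
#' Computes the first `n_pcs` principal components of the beta matrix
#' (samples as observations, features centred) and flags samples lying more
#' than `k` robust SDs (median absolute deviation scaled by 1.4826) from
#' their sex group's median in any component. A deterministic surrogate for
#' visual inspection of PC scatterplots; `k = Inf` disables flagging.
#'
#' @param beta CpG x sample beta matrix.
#' @param sex sex label per sample.
#' @param n_pcs number of leading components to inspect (default 2).
#' @param k flagging threshold in robust SDs (default 3).
#' @return character vector of flagged sample ids.
#' @export
pc_outlier_flag <- function(beta, sex, n_pcs = 2, k = 3) {
  if (all(apply(beta, 1, stats::var, na.rm = TRUE) < 1e-12))
    stop("degenerate (constant) beta matrix")
  sex <- as.character(sex)
  if (any(table(sex) < 5)) stop("need at least 5 samples per sex group")
  if (is.infinite(k)) return(character(0))
  pcs <- stats::prcomp(t(beta), center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  flagged <- character(0)
  for (s in unique(sex)) {
    rows <- which(sex == s)
    for (pc in seq_len(ncol(pcs))) {
      v <- pcs[rows, pc]
      scale <- stats::mad(v)
      if (scale < 1e-12) next
      far <- abs(v - stats::median(v)) > k * scale
      flagged <- union(flagged, colnames(beta)[rows[far]])
    }
  }
  flagged
}

#' Run the full methylation QC pipeline
#'
#' Fixed order: probe filters, sample filters, twin deduplication,
#' empirical Bayes batch adjustment (with sex as the protected covariate),
#' gold-standard quantile normalization (reference: per-probe mean across
#' retained samples), PC-based outlier flagging. Returns the adjusted
#' matrix and a QC report with one primary reason per dropped id.
#'
#' @param beta,detection_p CpG x sample matrices.
#' @param intensity,samplesheet per-sample metadata (see
#'   [filter_samples()]; `samplesheet` must carry `plate` and `family_id`).
#' @param x_probe_ids X-chromosome probe ids.
#' @param cross_reactive_ids cross-reactive probe ids.
#' @param pc_k robust-SD threshold for the PC outlier flag.
#' @param seed seed for twin selection.
#' @return list: `beta` (adjusted, retained probes x retained samples),
#'   `report` (dropped probes/samples with reasons, counts per step).
#' @export
run_methqc <- function(beta, detection_p, intensity, samplesheet,
                       x_probe_ids, cross_reactive_ids = character(0),
                       pc_k = 3, seed = 1) {
  pf <- filter_probes(detection_p, cross_reactive_ids)
  beta <- beta[pf$retained, , drop = FALSE]
  detection_p <- detection_p[pf$retained, , drop = FALSE]

  sf <- filter_samples(detection_p, intensity, samplesheet, beta,
                       x_probe_ids)
  keep <- sf$retained
  tw <- dedup_twins(samplesheet[samplesheet$sample_id %in% keep, ,
                                drop = FALSE], seed = seed)
  keep <- intersect(keep, tw$retained)
  beta <- beta[, keep, drop = FALSE]

  sheet <- samplesheet[match(keep, samplesheet$sample_id), , drop = FALSE]
  beta_adj <- eb_batch_adjust(beta, sheet$plate,
                              covariates = data.frame(sex = sheet$reported_sex))
  reference <- rowMeans(beta_adj)
  beta_norm <- normalize_to_gold_standard(beta_adj, reference)
  flagged <- pc_outlier_flag(beta_norm, sheet$reported_sex, k = pc_k)
  keep_final <- setdiff(keep, flagged)
  beta_final <- beta_norm[, keep_final, drop = FALSE]

  dropped_samples <- rbind(
    sf$dropped, tw$dropped,
    if (length(flagged))
      data.frame(id = flagged, reason = "pc_outlier",
                 stringsAsFactors = FALSE)
  )
  list(
    beta = beta_final,
    report = list(
      dropped_probes = pf$dropped,
      dropped_samples = dropped_samples,
      n_probes_retained = nrow(beta_final),
      n_samples_retained = ncol(beta_final),
      steps = c(probe_filter = length(pf$retained),
                sample_filter = length(sf$retained),
                twin_dedup = length(keep),
                pc_outlier = length(keep_final))
    )
  )
}
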