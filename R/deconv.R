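# Reference-based placental cell-type deconvolution by constrained
# projection: nonnegative least squares against a reference panel with the
# weights summing to at most one.

#' Estimate cell-type proportions by constrained projection
#'
#' Solves, per sample, `minimize ||b - R w||^2` subject to `w >= 0` and
#' `sum(w) <= 1` as a quadratic program, where `R` is the reference panel
#' restricted to the CpGs present in the sample. Weights are reported
#' unnormalized together with their sum; `renormalize = TRUE` rescales each
#' sample to `sum(w) = 1` for downstream covariate use.
#'
#' @param beta numeric matrix (panel CpGs x samples) or a named vector for
#'   a single sample; row names must match panel CpG ids. Missing CpGs are
#'   dropped pairwise per sample, but at least 80% of panel CpGs must be
#'   present overall.
#' @param panel reference matrix, CpGs x cell types, no missing entries.
#' @param renormalize rescale weights to sum to one.
#' @return data frame with one row per sample: `sample_id`, one column per
#'   cell type, and `sum`.
#' @export
estimate_proportions <- function(beta, panel, renormalize = FALSE) {
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = 1,
                                         dimnames = list(names(beta), "s1"))
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("s%03d", seq_len(ncol(beta)))
  if (anyNA(panel)) stop("reference panel must have no missing entries")
  if (nrow(panel) < 2 * ncol(panel))
    stop("reference panel needs at least twice as many CpGs as cell types")
  common <- intersect(rownames(panel), rownames(beta))
  if (length(common) < 0.8 * nrow(panel))
    stop("fewer than 80% of panel CpGs present in the sample matrix")
  beta <- beta[common, , drop = FALSE]
  panel <- panel[common, , drop = FALSE]
  k <- ncol(panel)

  out <- matrix(NA_real_, ncol(beta), k,
                dimnames = list(colnames(beta), colnames(panel)))
  # constraints: w_j >= 0 (identity rows), -sum(w) >= -1
  Amat <- cbind(diag(k), -1)
  bvec <- c(rep(0, k), -1)
  for (j in seq_len(ncol(beta))) {
    b <- beta[, j]
    ok <- !is.na(b)
    R <- panel[ok, , drop = FALSE]
    if (qr(R)$rank < k)
      stop("reference panel rank-deficient after dropping missing CpGs ",
           "for sample ", colnames(beta)[j])
    D <- crossprod(R)
    d <- crossprod(R, b[ok])
    sol <- quadprog::solve.QP(D, d, Amat, bvec)
    w <- pmax(sol$solution, 0)
    out[j, ] <- w
  }
  sums <- rowSums(out)
  if (renormalize) out <- out / sums
  data.frame(sample_id = rownames(out), out, sum = sums,
             row.names = NULL, stringsAsFactors = FALSE,
             check.names = FALSE)
}
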