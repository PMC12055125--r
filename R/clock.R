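# Epigenetic gestational age: linear clocks over clock-CpG beta values,
# elastic-net clock training for synthetic benchmarking, and intrinsic /
# extrinsic gestational age acceleration residuals. Positive residual =
# acceleration (faster biological aging than chronologic GA), negative =
# deceleration.

#' Construct a clock model
#'
#' @param intercept intercept, weeks.
#' @param weights named numeric vector of weights (weeks per unit beta),
#'   names are CpG ids.
#' @return list of class `gw_clock`.
#' @export
clock_model <- function(intercept, weights) {
  ids <- names(weights)
  if (length(weights) > 0 && (is.null(ids) || anyDuplicated(ids)))
    stop("clock weights must have unique CpG id names")
  structure(list(intercept = as.numeric(intercept),
                 weights = weights, cpgs = ids), class = "gw_clock")
}

#' Predict epigenetic gestational age
#'
#' `EGA_i = intercept + sum_j w_j beta_ij` over the clock CpGs. Every model
#' CpG must be present; there is no imputation.
#'
#' @param beta CpG x sample beta matrix containing all clock CpGs.
#' @param model a [clock_model()].
#' @return named numeric vector of epigenetic GA, weeks.
#' @export
predict_ega <- function(beta, model) {
  missing <- setdiff(model$cpgs, rownames(beta))
  if (length(missing))
    stop("clock CpGs absent from beta matrix: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)",
                                          length(missing) - 5))
  if (length(model$cpgs) == 0L)
    return(stats::setNames(rep(model$intercept, ncol(beta)),
                           colnames(beta)))
  sub <- beta[model$cpgs, , drop = FALSE]
  stats::setNames(model$intercept +
                    as.numeric(crossprod(sub, model$weights)),
                  colnames(beta))
}

#' Train a gestational age clock by elastic net
#'
#' Regresses chronologic gestational age on CpG beta values with an
#' elastic-net penalty; the penalty strength is chosen by 10-fold
#' cross-validation (seeded fold assignment) unless `lambda` is supplied.
#' Only CpGs with nonzero coefficients enter the returned model.
#'
#' @param beta CpG x sample training beta matrix.
#' @param ga chronologic gestational age per training sample, weeks.
#' @param alpha elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param lambda optional fixed penalty; overrides cross-validation.
#' @param nfolds cross-validation folds.
#' @param seed seed for the fold assignment.
#' @return a [clock_model()].
#' @export
train_clock <- function(beta, ga, alpha = 0.5, lambda = NULL, nfolds = 10,
                        seed = 1) {
  if (ncol(beta) < 50) stop("need at least 50 training samples")
  if (stats::var(ga) < 1e-12) stop("constant gestational age vector")
  x <- t(beta)
  if (is.null(lambda)) {
    set.seed(gw_stream_seed(seed, "clock"))
    foldid <- sample(rep_len(seq_len(nfolds), length(ga)))
    cv <- glmnet::cv.glmnet(x, ga, alpha = alpha, foldid = foldid)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, ga, alpha = alpha)
  }
  cf <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))
  w <- cf[-1, 1]
  w <- w[w != 0]
  clock_model(intercept = cf[1, 1], weights = w)
}

# OLS residuals with rank and sample-size guards shared by the intrinsic
# and extrinsic residual computations.
gw_ols_residuals <- function(y, X, min_extra = 10) {
  keep <- stats::complete.cases(cbind(y, X))
  if (sum(keep) < ncol(X) + min_extra)
    stop("need at least ", ncol(X) + min_extra, " complete samples, have ",
         sum(keep))
  Xk <- X[keep, , drop = FALSE]
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    bad <- colnames(Xk)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("collinear regression design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  res <- rep(NA_real_, length(y))
  res[keep] <- stats::lm.fit(Xk, y[keep])$residuals
  names(res) <- rownames(X)
  res
}

#' Intrinsic gestational age acceleration residuals
#'
#' Residual of a linear regression of epigenetic GA on chronologic GA
#' adjusting for estimated cell-type proportions: age acceleration at the
#' cellular level, unconfounded by cell-composition differences. One cell
#' type (the largest compartment, syncytiotrophoblast, by default) is
#' dropped to break the sum-to-one collinearity of the proportions.
#'
#' @param ega epigenetic GA per sample, weeks.
#' @param cga chronologic GA per sample, weeks.
#' @param cell_proportions matrix or data frame of cell-type proportions,
#'   one row per sample, columns named by cell type.
#' @param drop_type cell-type column excluded from the design.
#' @return named residual vector (weeks); positive = acceleration.
#' @export
compute_intrinsic <- function(ega, cga, cell_proportions,
                              drop_type = "syncytiotrophoblast") {
  cp <- as.matrix(cell_proportions)
  if (drop_type %in% colnames(cp))
    cp <- cp[, setdiff(colnames(cp), drop_type), drop = FALSE]
  X <- cbind(intercept = 1, cga = cga, cp)
  rownames(X) <- names(ega)
  gw_ols_residuals(ega, X)
}

#' Extrinsic gestational age acceleration residuals
#'
#' Residual of a univariate linear regression of epigenetic GA on
#' chronologic GA; incorporates cell-composition differences.
#'
#' @inheritParams compute_intrinsic
#' @return named residual vector (weeks); positive = acceleration.
#' @export
compute_extrinsic <- function(ega, cga) {
  X <- cbind(intercept = 1, cga = cga)
  rownames(X) <- names(ega)
  gw_ols_residuals(ega, X, min_extra = 0)
}

#' Epigenetic and chronologic GA with acceleration residuals
#'
#' @inheritParams compute_intrinsic
#' @return data frame: `sample_id`, `ega_weeks`, `cga_weeks`,
#'   `intrinsic_gaa`, `extrinsic_gaa`.
#' @export
compute_age_accel <- function(ega, cga, cell_proportions,
                              drop_type = "syncytiotrophoblast") {
  data.frame(
    sample_id = names(ega),
    ega_weeks = as.numeric(ega), cga_weeks = as.numeric(cga),
    intrinsic_gaa = as.numeric(
      compute_intrinsic(ega, cga, cell_proportions, drop_type)),
    extrinsic_gaa = as.numeric(compute_extrinsic(ega, cga)),
    stringsAsFactors = FALSE
  )
}
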