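# Weekly distributed lag models over the unified 48-week axis (13
# preconception weeks + pregnancy weeks 1-35; pregnancy weeks 36-39 are
# structurally excluded so preterm births do not create missingness at the
# end of the axis). The weekly coefficient curve is constrained to a
# polynomial or natural-cubic-spline basis, the basis order is selected by
# AIC, and critical windows are maximal runs of weeks whose pointwise CI
# excludes zero.

#' Build a lag-coefficient basis
#'
#' Polynomial bases are powers 0..degree of the lag index centred to mean
#' zero and scaled to unit SD (numerical conditioning); spline bases are a
#' constant column plus a natural cubic spline with boundary knots at lags
#' 1 and `n_lags` and internal knots at equally spaced quantiles, `order`
#' columns in total.
#'
#' @param kind `"polynomial"` or `"natural_cubic_spline"`.
#' @param order polynomial degree (0-6) or spline degrees of freedom (2-8).
#' @param n_lags number of weekly lags (default 48).
#' @return list of class `gw_lag_basis`: `kind`, `order`, `B`
#'   (`n_lags` x q matrix, full column rank).
#' @export
build_lag_basis <- function(kind = c("polynomial", "natural_cubic_spline"),
                            order, n_lags = 48) {
  kind <- match.arg(kind)
  lag <- seq_len(n_lags)
  if (kind == "polynomial") {
    if (order < 0 || order > 6) stop("polynomial degree must be in 0..6")
    z <- (lag - mean(lag)) / stats::sd(lag)
    B <- outer(z, 0:order, `^`)
    colnames(B) <- paste0("poly", 0:order)
  } else {
    if (order < 2 || order > 8) stop("spline df must be in 2..8")
    S <- splines::ns(lag, df = order - 1, Boundary.knots = c(1, n_lags))
    B <- cbind(const = 1, unclass(S))
    colnames(B) <- c("const", paste0("ns", seq_len(order - 1)))
  }
  stopifnot(qr(B)$rank == ncol(B))
  structure(list(kind = kind, order = order, n_lags = n_lags, B = B),
            class = "gw_lag_basis")
}

#' Fit a weekly distributed lag model
#'
#' OLS of the outcome on `[covariate dummies | X B]`, where `X` is the
#' n x 48 weekly exposure matrix and `B` the lag basis: current and past
#' weekly levels enter one model simultaneously. Participants with any
#' missing week (or incomplete covariates) are dropped and counted. Weekly
#' effects `theta = B eta` and their pointwise t-based CIs are reported per
#' `scale_per` (10) concentration units;
#' `AIC = n log(RSS/n) + 2 (p + 1)`.
#'
#' @param outcome residual outcome vector, weeks.
#' @param weekly n x `n_lags` matrix of weekly exposures on the unified
#'   axis.
#' @param covariates optional covariate data frame (standard roster).
#' @param basis a [build_lag_basis()].
#' @param scale_per report scale (default 10 concentration units).
#' @param conf_level pointwise confidence level.
#' @return list of class `gw_dlm_fit`: `eta`, `cov_eta`, `weekly_effects`
#'   (data frame `unified_week`, `pregnancy_week`, `estimate`, `se`,
#'   `ci_low`, `ci_high`), `aic`, `n_used`, `n_dropped`, `basis`,
#'   `df_residual`.
#' @export
fit_dlm <- function(outcome, weekly, covariates = NULL, basis,
                    scale_per = 10, conf_level = 0.95) {
  stopifnot(inherits(basis, "gw_lag_basis"),
            ncol(weekly) == basis$n_lags)
  n_all <- length(outcome)
  if (!is.null(covariates)) {
    cv <- gw_covariate_frame(covariates)
    X0 <- stats::model.matrix(~ ., data = cv)
  } else {
    X0 <- matrix(1, n_all, 1, dimnames = list(NULL, "(Intercept)"))
  }
  keep <- stats::complete.cases(cbind(outcome, weekly)) &
    stats::complete.cases(X0)
  n <- sum(keep)
  XB <- weekly[keep, , drop = FALSE] %*% basis$B
  colnames(XB) <- paste0("lagb", seq_len(ncol(XB)))
  D <- cbind(X0[keep, , drop = FALSE], XB)
  p <- ncol(D)
  if (n < p + 10)
    stop("too few complete participants (", n, ") for ", p, " parameters")
  qrD <- qr(D)
  if (qrD$rank < p) stop("rank-deficient distributed lag design")
  cf <- qr.coef(qrD, outcome[keep])
  res <- outcome[keep] - D %*% cf
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrD))
  eta_idx <- (p - ncol(XB) + 1):p
  eta <- cf[eta_idx]
  cov_eta <- sigma2 * XtXinv[eta_idx, eta_idx, drop = FALSE]

  theta <- as.vector(basis$B %*% eta) * scale_per
  var_theta <- rowSums((basis$B %*% cov_eta) * basis$B) * scale_per^2
  se <- sqrt(pmax(var_theta, 0))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - p)
  uw <- seq_len(basis$n_lags)
  weekly_effects <- data.frame(
    unified_week = uw,
    pregnancy_week = ifelse(uw > 13, uw - 13L, NA_integer_),
    estimate = theta, se = se,
    ci_low = theta - tq * se, ci_high = theta + tq * se
  )
  structure(list(
    eta = eta, cov_eta = cov_eta, weekly_effects = weekly_effects,
    aic = n * log(rss / n) + 2 * (p + 1),
    n_used = n, n_dropped = n_all - n, basis = basis,
    df_residual = n - p, scale_per = scale_per, conf_level = conf_level
  ), class = "gw_dlm_fit")
}

#' Select the lag basis order by AIC
#'
#' Fits every candidate order and returns the fit with minimum AIC; exact
#' ties go to the smaller order, then to the earlier candidate. All
#' candidate AICs are returned for inspection.
#'
#' @inheritParams fit_dlm
#' @param kind basis kind passed to [build_lag_basis()].
#' @param orders integer vector of candidate orders; a single candidate is
#'   returned unconditionally.
#' @return the winning `gw_dlm_fit`, with an `aic_table` data frame
#'   (`order`, `aic`, `error`) attached.
#' @export
select_basis <- function(outcome, weekly, covariates = NULL,
                         kind = "polynomial", orders = c(1, 2, 3, 4),
                         scale_per = 10, conf_level = 0.95) {
  if (length(orders) < 1) stop("need at least one candidate order")
  fits <- vector("list", length(orders))
  aics <- rep(NA_real_, length(orders))
  errs <- character(length(orders))
  for (i in seq_along(orders)) {
    fits[[i]] <- tryCatch(
      fit_dlm(outcome, weekly, covariates,
              build_lag_basis(kind, orders[i]), scale_per, conf_level),
      error = function(e) conditionMessage(e))
    if (is.character(fits[[i]])) errs[i] <- fits[[i]]
    else aics[i] <- fits[[i]]$aic
  }
  if (all(is.na(aics)))
    stop("all candidate orders failed: ",
         paste(unique(errs[nzchar(errs)]), collapse = "; "))
  ord <- order(aics, orders, seq_along(orders), na.last = TRUE)
  best <- fits[[ord[1]]]
  best$aic_table <- data.frame(order = orders, aic = aics, error = errs,
                               stringsAsFactors = FALSE)
  best
}

#' Extract critical windows from a distributed lag fit
#'
#' Weeks whose pointwise CI at level `1 - alpha` excludes zero are grouped
#' into maximal consecutive runs; each run is annotated with its sign and
#' peak week (the week of largest absolute effect within the run).
#' Unified-axis weeks 14-48 are reported as pregnancy weeks 1-35; weeks
#' 1-13 as preconception weeks.
#'
#' @param fit a `gw_dlm_fit`.
#' @param alpha significance level for the pointwise intervals.
#' @return data frame with one row per run: `start_week`, `end_week`,
#'   `sign`, `peak_week` (unified axis), `start_label`, `end_label`,
#'   `peak_label` (human-readable pregnancy/preconception weeks); zero rows
#'   when no CI excludes zero.
#' @export
extract_windows <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "gw_dlm_fit"))
  we <- fit$weekly_effects
  tq <- stats::qt(1 - alpha / 2, df = fit$df_residual)
  lo <- we$estimate - tq * we$se
  hi <- we$estimate + tq * we$se
  sig <- (lo > 0) | (hi < 0)
  lab <- function(w) {
    ifelse(w > 13, paste0("pregnancy_week_", w - 13),
           paste0("preconception_week_", w))
  }
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (i in which(runs$values)) {
    wk <- starts[i]:ends[i]
    peak <- wk[which.max(abs(we$estimate[wk]))]
    out[[length(out) + 1L]] <- data.frame(
      start_week = starts[i], end_week = ends[i],
      sign = ifelse(we$estimate[peak] > 0, "positive", "negative"),
      peak_week = peak,
      start_label = lab(starts[i]), end_label = lab(ends[i]),
      peak_label = lab(peak), stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L)
    return(data.frame(start_week = integer(0), end_week = integer(0),
                      sign = character(0), peak_week = integer(0),
                      start_label = character(0), end_label = character(0),
                      peak_label = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Restrict a cohort to full-term births
#'
#' Keeps chronologic gestational age at birth >= `ga_threshold` weeks
#' (inclusive).
#'
#' @param participants data frame with `ga_weeks`.
#' @param ga_threshold full-term threshold, weeks (default 37).
#' @return the retained subset, with attribute `n_dropped`.
#' @export
full_term_restrict <- function(participants, ga_threshold = 37) {
  keep <- participants$ga_weeks >= ga_threshold
  if (!any(keep)) stop("no full-term births remain")
  out <- participants[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
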