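#' @keywords internal
"_PACKAGE"

# Component RNG streams are derived from the master seed by fixed offsets so
# that, e.g., changing the number of participants never perturbs the station
# series. Offsets kept small so derived seeds stay well below 2^31.
.gw_stream_offsets <- c(
  stations = 101L, participants = 202L, methylation = 303L,
  panel = 404L, assoc = 505L, dlm = 606L, qc = 707L, clock = 808L
)

gw_stream_seed <- function(seed, component) {
  stopifnot(component %in% names(.gw_stream_offsets))
  (as.integer(seed) %% 2000000000L) + .gw_stream_offsets[[component]]
}

#' Logit transform with boundary clipping
#'
#' Methylation beta values live in \[0,1\]; analyses on the logit (M-value
#' like) scale clip to `[eps, 1-eps]` first to avoid infinities.
#'
#' @param p numeric vector or matrix of values in \[0,1\].
#' @param eps clipping offset.
#' @return values on the logit scale.
#' @keywords internal
gw_logit <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' @rdname gw_logit
#' @param x numeric values on the logit scale.
#' @keywords internal
gw_expit <- function(x) 1 / (1 + exp(-x))

# Truncated-normal draws by inverse-CDF sampling; exact for the bounds used
# here (no rejection loop, so draw counts are seed-stable).
gw_rtnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}
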