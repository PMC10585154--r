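#' Wrap phase angles into (-pi, pi]
#'
#' Maps arbitrary phase values onto the principal interval used by the
#' phase-contrast and oximetry routines.
#'
#' @param x Numeric vector or array of phase values in radians.
#' @return Object of the same shape with values in (-pi, pi].
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi  # convention: half-open on the left
  y
}

# Truncated normal draws by rejection; degenerate sd = 0 returns the clamped
# mean. Bounds may be vectors (e.g. per-subject upper bound).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (all(sd == 0)) {
    return(pmin(pmax(mean, lower), upper))
  }
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(100)) {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
  }
  pmin(pmax(x, lower), upper)
}

stop_bad <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

as_mask <- function(roi) {
  if (is.logical(roi)) return(roi)
  roi >= 0.5
}
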