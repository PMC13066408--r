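# Internal numeric helpers shared across modules.

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed; per-patient and
#' per-stage streams are derived by hashing the master seed together with small
#' integer indices, so adding patients or stages does not perturb existing
#' draws. The result is always a positive 32-bit integer.
#'
#' @param seed Master integer seed.
#' @param ... Integer indices naming the substream (e.g. patient number,
#'   stage code).
#' @return A positive integer usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483647
  for (id in ids) {
    s <- (s * 48271 + as.double(id) + 11) %% 2147483647
  }
  as.integer(s %% 2147483562 + 1)
}

# Wilson score interval for a binomial proportion. Used for VAF confidence
# intervals because panel depths vary and VAFs sit near 0/1 boundaries.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
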