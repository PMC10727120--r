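#' One-dimensional threshold-free cluster enhancement
#'
#' Enhances a 1-D statistic series by integrating cluster extent and height
#' over all thresholds: `score(p) = sum_h extent(h, p)^E * h^H * dh` over
#' thresholds `h = dh, 2*dh, ... <= x[p]`, where `extent(h, p)` is the
#' length of the contiguous run of values `>= h` containing `p`. With the
#' defaults `E = 0.5`, `H = 2` (the standard choices for this enhancement)
#' the score of an isolated peak of height `h0` approaches `h0^3 / 3` as
#' `dh -> 0`. The series is assumed oriented so that the hypothesized
#' direction is positive (negate it for negative-tail tests); values below
#' zero never contribute. Missing values are treated as 0, so they break
#' cluster extent but are not themselves enhanced.
#'
#' @param x numeric 1-D statistic series.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; default `max(x) / nsteps`.
#' @param nsteps number of threshold steps used when `dh` is NULL.
#' @return numeric vector of enhanced scores, same length as `x`.
#' @export
tfce_1d <- function(x, E = 0.5, H = 2, dh = NULL, nsteps = 100) {
  x <- as.numeric(x)
  x[!is.finite(x)] <- 0
  mx <- max(x)
  if (mx <= 0) return(numeric(length(x)))
  if (is.null(dh)) dh <- mx / nsteps
  if (!is.numeric(dh) || length(dh) != 1 || dh <= 0)
    stop_invalid("`dh` must be a positive scalar")
  score <- numeric(length(x))
  h <- dh
  while (h <= mx + 1e-12) {
    above <- x >= h - 1e-12
    r <- rle(above)
    ext <- rep(r$lengths, r$lengths)
    score <- score + ifelse(above, ext^E * h^H * dh, 0)
    h <- h + dh
  }
  score
}
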