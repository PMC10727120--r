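#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats rnorm runif setNames approx sd var coef vcov qnorm plogis
#' @importFrom utils head tail
NULL

# stop with a consistent class so callers can distinguish validation errors
stop_invalid <- function(msg) rlang::abort(msg, class = "eegdyn_invalid")
stop_numerical <- function(msg) rlang::abort(msg, class = "eegdyn_numerical")

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

#' Spectral radius of a square matrix
#' @param A a square numeric matrix
#' @return largest eigenvalue modulus
#' @keywords internal
spectral_radius <- function(A) {
  if (all(dim(A) == 2)) return(max(Mod(eig2x2(A)$values)))
  max(Mod(eigen(A, only.values = TRUE)$values))
}

# closed-form eigendecomposition of a real 2x2 matrix; much faster than
# eigen() in the per-window hot loops. Returns complex eigenvalues, the
# real parts of unit-norm eigenvectors (columns), and a complex-pair flag.
eig2x2 <- function(A) {
  a <- A[1, 1]; b <- A[1, 2]; c <- A[2, 1]; d <- A[2, 2]
  tr <- a + d; det <- a * d - b * c
  disc <- tr * tr / 4 - det
  if (disc >= 0) {
    s <- sqrt(disc)
    vals <- complex(real = c(tr / 2 + s, tr / 2 - s), imaginary = c(0, 0))
    cplx <- FALSE
  } else {
    s <- sqrt(-disc)
    vals <- complex(real = c(tr / 2, tr / 2), imaginary = c(s, -s))
    cplx <- TRUE
  }
  V <- matrix(0, 2, 2)
  for (k in 1:2) {
    lr <- Re(vals[k])
    # rows of (A - lambda I) are orthogonal to the eigenvector (real part)
    if (abs(b) >= abs(c) && (abs(b) > 1e-300 || abs(lr - a) > 1e-300)) {
      v <- c(b, lr - a)
    } else if (abs(c) > 1e-300 || abs(lr - d) > 1e-300) {
      v <- c(lr - d, c)
    } else {
      v <- c(k == 1, k == 2)  # diagonal matrix: coordinate axes
    }
    nv <- sqrt(sum(v^2))
    V[, k] <- if (nv > 0) v / nv else c(k == 1, k == 2)
  }
  list(values = vals, vectors = V, complex = cplx)
}

# stationary covariance of x(t+1) = A x(t) + e, e ~ N(0, s2 I), via the
# discrete Lyapunov equation vec(P) = (I - A (x) A)^-1 vec(s2 I)
stationary_cov <- function(A, s2) {
  d <- nrow(A)
  M <- diag(d * d) - kronecker(A, A)
  matrix(solve(M, as.vector(diag(s2, d))), d, d)
}

# derive a reproducible 31-bit sub-seed from a base seed and integer tags
sub_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (tag in tags) s <- (s * 48271 + as.double(tag) * 9973 + 1) %% 2147483647
  as.integer(s)
}

#' Analysis-rate time axis for an event-locked window
#'
#' Sample times (ms) on the sampling grid aligned so that t = 0 ms (the
#' locking event) falls on a sample whenever it lies inside the window.
#' With inclusive endpoints this yields `round((end - start)/1000 * fs) + 1`
#' samples for windows whose edges sit on the grid (e.g. 31 samples for
#' -500..500 ms at 30 Hz).
#'
#' @param start_ms,end_ms window edges in ms relative to the lock event.
#' @param fs sampling rate in Hz.
#' @return numeric vector of sample times in ms.
#' @export
time_grid <- function(start_ms, end_ms, fs) {
  step <- 1000 / fs
  k <- seq(ceiling(start_ms / step - 1e-9), floor(end_ms / step + 1e-9))
  k * step
}
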