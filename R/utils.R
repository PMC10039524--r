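#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps (global seed, stage label) to a 31-bit integer so
#' that each pipeline stage receives an independent, reproducible stream.
#'
#' @param seed global integer seed.
#' @param label character stage label.
#' @return integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Wrap angles to [-pi, pi)
#' @param x numeric vector/array of angles in radians.
#' @return Angles wrapped to `[-pi, pi)`.
#' @export
wrap_phase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Circular resultant length
#'
#' Mean resultant length of a sample of angles; 1 for perfectly concentrated
#' phases, near 0 for phases spread over the whole circle.
#'
#' @param theta angles in radians (NAs dropped).
#' @return scalar in `[0, 1]`.
#' @export
resultant_length <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (!length(theta)) return(NA_real_)
  Mod(mean(exp(1i * theta)))
}

## circular mean of angles
circ_mean <- function(theta) {
  theta <- theta[is.finite(theta)]
  Arg(mean(exp(1i * theta)))
}

#' Analytic signal via the discrete Hilbert transform
#'
#' FFT implementation of the analytic signal: negative frequencies are
#' zeroed, positive frequencies doubled (DC and Nyquist untouched).  Operates
#' on columns when given a matrix.
#'
#' @param x numeric vector, or matrix with time along rows.
#' @return complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    h <- hilbert_weights(n)
    X <- stats::mvfft(x)
    return(stats::mvfft(X * h, inverse = TRUE) / n)
  }
  n <- length(x)
  h <- hilbert_weights(n)
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

hilbert_weights <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

## truncated-normal sampler (lower truncation only), inverse-CDF method
rtruncnorm_lower <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p0, 1)
  stats::qnorm(u, mean, sd)
}

## smooth a 2-D white-noise grid with a Gaussian kernel via FFT convolution.
## The grid is zero-padded by 3 sigma before the (circular) convolution and
## cropped afterwards, so opposite edges are NOT treated as neighbours --
## wrap-around would otherwise correlate electrodes at opposite corners.
## Used for envelopes and spatially correlated noise; sigma in pixels.
smooth_field_2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  pad <- ceiling(3 * sigma)
  nr0 <- nrow(mat); nc0 <- ncol(mat)
  big <- matrix(0, nr0 + 2 * pad, nc0 + 2 * pad)
  big[pad + seq_len(nr0), pad + seq_len(nc0)] <- mat
  sm <- smooth_field_periodic(big, sigma)
  sm[pad + seq_len(nr0), pad + seq_len(nc0)]
}

## draw a stationary Gaussian random field with Gaussian correlation of
## width sigma (pixels): white noise on a 3-sigma-padded grid, periodic
## smoothing, crop.  Unit marginal variance up to smoothing normalisation
## (callers rescale); consumes (nr+2p)*(nc+2p) normal deviates.
gaussian_random_field <- function(nr, nc, sigma) {
  if (sigma <= 0) return(matrix(stats::rnorm(nr * nc), nr, nc))
  ## cap the padding: beyond ~100 px the residual wrap-around correlation
  ## of the cropped interior is negligible, while an uncapped 3-sigma pad
  ## for near-global correlation lengths would demand enormous FFTs
  pad <- min(ceiling(3 * sigma), max(100L, 2L * max(nr, nc)))
  z <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
              nr + 2 * pad, nc + 2 * pad)
  sm <- smooth_field_periodic(z, sigma)
  sm[pad + seq_len(nr), pad + seq_len(nc)]
}

smooth_field_periodic <- function(mat, sigma) {
  nr <- nrow(mat); nc <- ncol(mat)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  ## Gaussian kernel in Fourier space: exp(-2 pi^2 sigma^2 f^2)
  gr <- exp(-2 * pi^2 * sigma^2 * fr^2)
  gc <- exp(-2 * pi^2 * sigma^2 * fc^2)
  G <- outer(gr, gc)
  Re(stats::fft(stats::fft(mat) * G, inverse = TRUE)) / (nr * nc)
}

## null-coalescing helper
`%||%` <- function(a, b) if (is.null(a)) b else a
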