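## -- IIR filter design and zero-phase filtering ------------------------------
##
## No DSP package ships with this R installation, so the second-order
## Butterworth band-pass (bilinear transform of the analog prototype) and the
## forward-backward zero-phase filter are implemented here and verified in
## tests against the analytic frequency response.

## polynomial coefficients (descending powers) from roots, real part only
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

#' Design a digital Butterworth band-pass filter
#'
#' Analog Butterworth prototype of order `order`, band-pass transformed and
#' discretised with the bilinear transform (with frequency pre-warping).  The
#' resulting transfer function has `2 * order + 1` numerator and denominator
#' coefficients; gain is normalised to 1 at the (warped) geometric centre
#' frequency.
#'
#' @param low,high band edges in Hz (`0 < low < high < fs / 2`).
#' @param fs sampling rate in Hz.
#' @param order analog prototype order (default 2, i.e. a 4th-order digital
#'   filter).
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low, high, fs, order = 2L) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  ## pre-warped analog edges
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  ## analog prototype poles (unit Butterworth circle, left half-plane)
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  ## low-pass -> band-pass: each pole splits into a quadratic pair
  p_bp <- c()
  for (p in p_proto) {
    pb <- p * bw / 2
    disc <- sqrt(pb^2 - w0^2 + 0i)
    p_bp <- c(p_bp, pb + disc, pb - disc)
  }
  ## bilinear transform
  fs2 <- 2 * fs
  zp <- (fs2 + p_bp) / (fs2 - p_bp)
  ## band-pass zeros: `order` at z = +1 and `order` at z = -1
  zz <- c(rep(1, order), rep(-1, order))
  a <- poly_from_roots(zp)
  b <- poly_from_roots(zz)
  ## unit gain at the warped centre frequency
  f0 <- fs / pi * atan(w0 / fs2)
  g <- filter_gain(b, a, f0, fs)
  list(b = b / g, a = a)
}

#' Frequency-response magnitude of a digital filter
#'
#' @param b,a transfer-function coefficients.
#' @param f frequencies in Hz (vectorised).
#' @param fs sampling rate in Hz.
#' @return `|H(e^{i 2 pi f / fs})|` at each frequency.
#' @export
filter_gain <- function(b, a, f, fs) {
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / fs)
    zp <- z^(0:(length(b) - 1))
    za <- z^(0:(length(a) - 1))
    Mod(sum(b * zp) / sum(a * za))
  }, numeric(1))
}

## direct-form-II-transposed IIR filter along columns of x (time x channels),
## vectorised across channels; zi is (order x channels) initial state
iir_filter <- function(b, a, x, zi = NULL) {
  n <- length(a)
  stopifnot(length(b) == n)
  nt <- nrow(x); nc <- ncol(x)
  z <- if (is.null(zi)) matrix(0, n - 1, nc) else zi
  y <- matrix(0, nt, nc)
  b0 <- b[1]; bi <- b[-1]; ai <- a[-1]
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b0 * xt + z[1, ]
    if (n > 2) {
      z[1:(n - 2), ] <- z[2:(n - 1), , drop = FALSE] +
        outer(bi[1:(n - 2)], xt) - outer(ai[1:(n - 2)], yt)
    }
    z[n - 1, ] <- bi[n - 1] * xt - ai[n - 1] * yt
    y[t, ] <- yt
  }
  list(y = y, z = z)
}

## steady-state initial filter state for a unit step (per scipy's lfilter_zi),
## so reflection-padded filtfilt has no start-up transient
filter_zi <- function(b, a) {
  n <- length(a)
  A <- matrix(0, n - 1, n - 1)
  A[, 1] <- -a[-1]
  if (n > 2) A[1:(n - 2), 2:(n - 1)] <- diag(n - 2)
  B <- b[-1] - b[1] * a[-1]
  solve(diag(n - 1) - A, B)
}

#' Zero-phase forward-backward filtering
#'
#' Applies the filter forward and then backward (Gustafsson-style odd
#' reflection padding with steady-state initial conditions), cancelling the
#' phase response.  Operates on each row of a channels x time matrix.
#'
#' @param b,a transfer-function coefficients.
#' @param x numeric vector or channels x time matrix.
#' @return filtered data, same shape as `x`.
#' @export
filtfilt <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  nt <- ncol(x)
  npad <- 3 * (length(a) - 1)
  if (nt <= npad)
    stop("signal too short for zero-phase filtering (need > ", npad, " samples)")
  ## odd reflection padding, time x channels orientation
  xt <- t(x)
  pre <- 2 * rep(xt[1, ], each = npad) - xt[(npad + 1):2, , drop = FALSE]
  post <- 2 * rep(xt[nt, ], each = npad) - xt[(nt - 1):(nt - npad), , drop = FALSE]
  ext <- rbind(pre, xt, post)
  zi <- filter_zi(b, a)
  fwd <- iir_filter(b, a, ext, zi = outer(zi, ext[1, ]))$y
  rev_in <- fwd[nrow(fwd):1, , drop = FALSE]
  bwd <- iir_filter(b, a, rev_in, zi = outer(zi, rev_in[1, ]))$y
  out <- bwd[nrow(bwd):1, , drop = FALSE]
  out <- t(out[(npad + 1):(npad + nt), , drop = FALSE])
  if (vec) out[1, ] else out
}

#' Delta-band zero-phase filtering of a recording
#'
#' Second-order Butterworth band-pass (default 1-4 Hz) applied per channel in
#' the forward and reverse directions, so the group delay is zero and the
#' delta-band phase structure used by all wave analyses is preserved.
#'
#' @param rec a [voltage_recording()].
#' @param low,high band edges in Hz.
#' @param order Butterworth prototype order.
#' @return A filtered [voltage_recording()] (provenance gains `"filtered"`).
#' @export
bandpass_delta <- function(rec, low = 1, high = 4, order = 2L) {
  stopifnot(inherits(rec, "voltage_recording"))
  des <- butter_bandpass(low, high, rec$sampling_rate, order)
  v <- filtfilt(des$b, des$a, rec$voltage)
  voltage_recording(v, rec$sampling_rate, rec$layout,
                    provenance = c(rec$provenance, "filtered"))
}

#' Remove large-amplitude artifacts
#'
#' Samples whose absolute value exceeds `threshold` (default 200 uV) are
#' replaced, per channel, by that channel's mean computed over the non-artifact
#' samples (computing the mean over all samples would let the artifact
#' contaminate its own replacement; set `use_all_samples = TRUE` for the
#' literal all-samples variant).  A channel consisting entirely of artifacts
#' is zeroed with a warning.
#'
#' @param rec a [voltage_recording()].
#' @param threshold artifact threshold in uV (> 0).
#' @param use_all_samples compute the replacement mean over all samples.
#' @return A cleaned [voltage_recording()] (provenance gains `"cleaned"`).
#' @export
remove_artifacts <- function(rec, threshold = 200, use_all_samples = FALSE) {
  stopifnot(inherits(rec, "voltage_recording"), threshold > 0)
  v <- rec$voltage
  bad <- abs(v) > threshold
  nbad <- rowSums(bad)
  for (ch in which(nbad > 0)) {
    idx <- bad[ch, ]
    if (all(idx)) {
      warning("channel ", ch, " is entirely artifacts; set to zero")
      v[ch, ] <- 0
    } else {
      m <- if (use_all_samples) mean(v[ch, ]) else mean(v[ch, !idx])
      v[ch, idx] <- m
    }
  }
  voltage_recording(v, rec$sampling_rate, rec$layout,
                    provenance = c(rec$provenance, "cleaned"))
}

#' Mean band-filtered voltage per frequency band
#'
#' Mean absolute voltage after zero-phase band-pass filtering in the five
#' canonical bands: delta (0.1-4 Hz), theta (4-7), alpha (7-12), beta
#' (12-30), gamma (30-80).  Bands whose upper edge reaches the Nyquist
#' frequency are dropped with a warning.  The delta band is implemented with
#' a 0.1 Hz high-pass edge for numerical stability; the spiral-detection
#' pipeline itself uses 1-4 Hz (see [bandpass_delta()]).
#'
#' @param rec a [voltage_recording()] (sampling rate > 160 Hz recommended to
#'   resolve gamma).
#' @param bands named list of `c(low, high)` edges in Hz.
#' @return data.frame with band, low_hz, high_hz, amplitude (uV).
#' @export
band_amplitudes <- function(rec,
                            bands = list(delta = c(0.1, 4), theta = c(4, 7),
                                         alpha = c(7, 12), beta = c(12, 30),
                                         gamma = c(30, 80))) {
  stopifnot(inherits(rec, "voltage_recording"))
  nyq <- rec$sampling_rate / 2
  keep <- vapply(bands, function(e) e[2] < nyq, logical(1))
  if (any(!keep))
    warning("dropping bands at/above Nyquist: ",
            paste(names(bands)[!keep], collapse = ", "))
  bands <- bands[keep]
  amp <- vapply(bands, function(e) {
    des <- butter_bandpass(e[1], e[2], rec$sampling_rate, 2L)
    mean(abs(filtfilt(des$b, des$a, rec$voltage)))
  }, numeric(1))
  data.frame(band = names(bands),
             low_hz = vapply(bands, `[`, numeric(1), 1),
             high_hz = vapply(bands, `[`, numeric(1), 2),
             amplitude = unname(amp), row.names = NULL)
}
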