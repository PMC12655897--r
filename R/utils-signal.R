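## Signal-processing primitives shared by the event-detection and cut-angle
## stages. Kept dependency-free: the design below is the textbook bilinear
## transform of the analog Butterworth prototype, validated in the test suite
## against an independent frequency-response oracle.

#' Design a digital low-pass Butterworth filter
#'
#' Returns transfer-function coefficients (b, a) of an order-`n` low-pass
#' Butterworth filter with cutoff `cutoff_hz` at sampling rate `fs`, obtained
#' by bilinear transform of the analog prototype with frequency pre-warping.
#'
#' @param n filter order (>= 1)
#' @param cutoff_hz cutoff frequency in Hz, 0 < cutoff_hz < fs/2
#' @param fs sampling frequency in Hz
#' @return list with numeric vectors `b` (numerator) and `a` (denominator,
#'   a[1] == 1)
#' @keywords internal
butter_lowpass <- function(n, cutoff_hz, fs) {
  stopifnot(n >= 1, cutoff_hz > 0, cutoff_hz < fs / 2)
  # pre-warped analog cutoff
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)
  # analog Butterworth poles on the unit circle, scaled by wc
  k <- seq_len(n)
  theta <- pi * (2 * k + n - 1) / (2 * n)
  p <- wc * complex(real = cos(theta), imaginary = sin(theta))
  # bilinear transform: z-pole = (2fs + s) / (2fs - s)
  fs2 <- 2 * fs
  zp <- (fs2 + p) / (fs2 - p)
  # all n zeros map to z = -1
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, n)))
  # normalize DC gain to 1 (evaluate at z = 1)
  g <- sum(a) / sum(b)
  list(b = b * g, a = a)
}

# expand prod (x - r_i) into polynomial coefficients, highest power first
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

# direct-form-II-transposed IIR filter; x numeric, b/a coefficient vectors
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b); na <- length(a)
  nord <- max(nb, na) - 1
  b <- c(b, rep(0, nord + 1 - nb))
  a <- c(a, rep(0, nord + 1 - na))
  y <- numeric(length(x))
  z <- numeric(nord)
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nord > 1) {
      for (j in seq_len(nord - 1)) {
        z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
      }
    }
    z[nord] <- b[nord + 1] * xi - a[nord + 1] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward with reflected-edge padding so the
#' output has no phase lag — event timing must not be shifted by smoothing.
#'
#' @param b,a transfer-function coefficients from [butter_lowpass()]
#' @param x numeric signal
#' @return filtered signal, same length as `x`
#' @keywords internal
filtfilt_zero_phase <- function(b, a, x) {
  n <- length(x)
  npad <- min(n - 1, 3 * (max(length(a), length(b)) - 1))
  if (npad < 1) return(x)
  # odd reflection reduces edge transients
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xx <- c(pre, x, post)
  y <- iir_filter(b, a, xx)
  y <- rev(iir_filter(b, a, rev(y)))
  y[seq(npad + 1, npad + n)]
}

#' Local extrema with prominence and minimum-separation constraints
#'
#' Finds strict local maxima of `x`, computes each peak's topographic
#' prominence, discards peaks below `min_prominence`, then greedily enforces a
#' minimum index separation keeping the most prominent peaks first.
#'
#' @param x numeric signal
#' @param min_prominence minimum prominence (signal units)
#' @param min_separation minimum distance between retained peaks, in samples
#' @return integer vector of peak indices, sorted increasing (may be empty)
#' @keywords internal
find_peaks <- function(x, min_prominence = 0, min_separation = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(idx) == 0) return(integer(0))
  prom <- vapply(idx, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) == 0) return(integer(0))
  # enforce separation, most prominent first
  ord <- order(-prom)
  chosen <- integer(0)
  for (i in idx[ord]) {
    if (all(abs(chosen - i) >= min_separation)) chosen <- c(chosen, i)
  }
  sort(chosen)
}

peak_prominence <- function(x, i) {
  h <- x[i]
  # walk left until a higher sample; key col is the minimum along the way
  left <- x[seq_len(i - 1)]
  hi_l <- which(left > h)
  lmin <- if (length(hi_l)) min(left[seq(max(hi_l), i - 1)]) else min(left)
  right <- x[seq(i + 1, length(x))]
  hi_r <- which(right > h)
  rmin <- if (length(hi_r)) min(right[seq_len(min(hi_r))]) else min(right)
  h - max(lmin, rmin)
}

find_troughs <- function(x, min_prominence = 0, min_separation = 1) {
  find_peaks(-x, min_prominence, min_separation)
}

# central differences with one-sided ends; returns dx/dt given sample rate
central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop("central_diff needs at least 2 samples")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# exact (non-partial) enumeration check
enum_arg <- function(x, choices) {
  nm <- deparse(substitute(x))
  if (length(x) != 1 || !x %in% choices) {
    stop(sprintf("invalid %s: must be one of %s", nm,
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
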