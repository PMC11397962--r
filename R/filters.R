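#' Design a digital Butterworth band-pass filter
#'
#' Designs an order-`order` Butterworth band-pass filter (so `2 * order`
#' poles in the digital filter) by the classic analog-prototype route:
#' Butterworth low-pass prototype, low-pass to band-pass transform with
#' pre-warped edge frequencies, then the bilinear transform.
#'
#' @param order Prototype filter order (4 gives the standard 8-pole
#'   band-pass used throughout surface-EMG preprocessing).
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @return A list with numeric vectors `b` (numerator) and `a`
#'   (denominator, `a[1] == 1`) of length `2 * order + 1`.
#' @examples
#' bt <- butter_bandpass(4, 10, 400, fs = 1920)
#' length(bt$b)
#' @export
butter_bandpass <- function(order, low, high, fs) {
  if (!(is.numeric(low) && is.numeric(high) && is.numeric(fs)))
    stop("band edges and fs must be numeric")
  if (!(low > 0 && high > low && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (Nyquist)")
  if (order < 1) stop("order must be >= 1")

  # pre-warped analog edges (bilinear with T = 2)
  W1 <- tan(pi * low / fs)
  W2 <- tan(pi * high / fs)
  W0 <- sqrt(W1 * W2)
  BW <- W2 - W1

  # Butterworth low-pass prototype poles, unit cutoff
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p_lp <- complex(real = -sin(theta), imaginary = cos(theta))

  # low-pass -> band-pass: each prototype pole splits in two
  bq <- p_lp * BW / 2
  disc <- sqrt(bq^2 - W0^2)
  p_bp <- c(bq + disc, bq - disc)
  # band-pass zeros: `order` zeros at s = 0; gain BW^order
  gain_s <- BW^order

  # bilinear transform, T = 2: z = (1 + s)/(1 - s)
  z_p <- (1 + p_bp) / (1 - p_bp)
  gain_z <- gain_s * Re(1 / prod(1 - p_bp))
  # digital zeros: `order` at z = +1 (from s = 0), `order` at z = -1
  z_z <- c(rep(1 + 0i, order), rep(-1 + 0i, order))

  b <- Re(.poly_from_roots(z_z)) * gain_z
  a <- Re(.poly_from_roots(z_p))
  list(b = b, a = a / a[1])
}

.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0i) - c(0i, p) * ri
  p
}

#' Causal IIR filtering (direct difference equation)
#'
#' Applies `a[1] y[n] = sum(b * x[n:(n-nb+1)]) - sum(a[-1] * y[(n-1):...])`
#' with zero initial state, at C speed via [stats::filter()].
#'
#' @param b,a Filter coefficients, `a[1]` must be non-zero.
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @keywords internal
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  # FIR stage with explicit zero pre-padding so no leading NAs appear
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# steady-state initial filter state for a unit-amplitude step input
# (solves (I - A') zi = B for the direct-form II transposed realization)
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  comp <- rbind(-a[2:n] / a[1],
                cbind(diag(1, n - 2), rep(0, n - 2)))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(1, n - 1) - t(comp), B)
}

# causal filtering with initial state z0 (zero-input response added by
# linearity: Y = (B X + Z0(z)) / A)
.iir_filter_state <- function(b, a, x, z0) {
  y <- iir_filter(b, a, x)
  delta <- c(1, numeric(length(x) - 1))
  y + iir_filter(z0, a, delta)
}

#' Zero-phase (forward-backward) filtering
#'
#' Filters forward and backward so the net phase response is zero and the
#' amplitude response is squared. Edge transients are controlled by
#' odd-symmetric reflection padding at both ends plus steady-state initial
#' conditions scaled to the first padded sample (so e.g. a constant input
#' settles immediately).
#'
#' @param b,a Filter coefficients.
#' @param x Numeric signal (length > 1).
#' @param padlen Reflection pad length; default scales with the filter
#'   length and is capped at `length(x) - 1`.
#' @return Zero-lag filtered signal, same length as `x`.
#' @export
filtfilt_emg <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (n < 2) stop("signal too short to filter")
  if (is.null(padlen)) padlen <- 30 * (max(length(a), length(b)) - 1)
  padlen <- min(padlen, n - 1)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- .lfilter_zi(b, a)
  y <- .iir_filter_state(b, a, ext, zi * ext[1])
  y <- rev(.iir_filter_state(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Band-pass filter a multichannel EMG recording
#'
#' Zero-lag Butterworth band-pass of every channel: the designed filter is
#' applied forward and backward ([filtfilt_emg()]), so the pass-band is
#' traversed twice (effective 8th-order magnitude for `order = 4`) with no
#' phase distortion. Labels and metadata are untouched.
#'
#' @param rec An [emg_recording()].
#' @param low,high Band edges in Hz (defaults 10 and 400, the standard
#'   surface-EMG band).
#' @param order Butterworth prototype order per pass (default 4).
#' @return An `emg_recording` of identical shape with filtered samples.
#' @export
bandpass_filter <- function(rec, low = 10, high = 400, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!(low > 0 && high > low && high < rec$fs / 2))
    stop("cutoffs must satisfy 0 < low < high < fs/2")
  bt <- butter_bandpass(order, low, high, rec$fs)
  # pad past the slowest (low-cutoff) pole's decay so edges settle
  padlen <- max(30 * (length(bt$a) - 1), ceiling(3 * rec$fs / low))
  out <- rec
  out$samples <- t(apply(rec$samples, 1, function(ch)
    filtfilt_emg(bt$b, bt$a, ch, padlen = padlen)))
  dimnames(out$samples) <- dimnames(rec$samples)
  out
}
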