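#' Digital filter specification for EEG preprocessing
#'
#' Describes the filter chain applied to a recording before epoching: an
#' optional mains-notch filter followed by a Butterworth band-pass.  The
#' defaults reproduce the 60 Hz notch and 2--60 Hz order-5 band-pass used
#' for the PhysioNet motor movement/imagery recipe.
#'
#' @param bandpass_low_hz,bandpass_high_hz Band-pass edges in Hz.
#' @param bandpass_order Butterworth prototype order (the band-pass filter
#'   has twice this many poles).
#' @param notch_freq_hz Centre frequency of the notch in Hz, or `NULL` to
#'   disable the notch stage.
#' @param notch_q Quality factor of the notch (centre / -3 dB bandwidth).
#' @return An object of class `"filter_spec"`.
#' @examples
#' filter_spec()                      # eegmmidb defaults: notch 60, band 2-60
#' filter_spec(notch_freq_hz = NULL)  # band-pass only
#' @export
filter_spec <- function(bandpass_low_hz = 2, bandpass_high_hz = 60,
                        bandpass_order = 5, notch_freq_hz = 60, notch_q = 30) {
  if (!is_scalar(bandpass_low_hz) || !is_scalar(bandpass_high_hz) ||
      bandpass_low_hz <= 0 || bandpass_low_hz >= bandpass_high_hz)
    stopf("need 0 < bandpass_low_hz < bandpass_high_hz")
  if (!is_count(bandpass_order)) stopf("bandpass_order must be a positive integer")
  if (!is.null(notch_freq_hz) && (!is_scalar(notch_freq_hz) || notch_freq_hz <= 0))
    stopf("notch_freq_hz must be positive or NULL")
  if (!is_scalar(notch_q) || notch_q <= 0) stopf("notch_q must be positive")
  structure(list(bandpass_low_hz = bandpass_low_hz,
                 bandpass_high_hz = bandpass_high_hz,
                 bandpass_order = as.integer(bandpass_order),
                 notch_freq_hz = notch_freq_hz, notch_q = notch_q),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec>\n")
  if (!is.null(x$notch_freq_hz))
    cat(sprintf("  notch: %g Hz (Q = %g)\n", x$notch_freq_hz, x$notch_q))
  cat(sprintf("  band-pass: Butterworth order %d, %g-%g Hz\n",
              x$bandpass_order, x$bandpass_low_hz, x$bandpass_high_hz))
  invisible(x)
}

#' Butterworth band-pass filter design
#'
#' Designs a digital Butterworth band-pass filter by the standard analog
#' prototype / band transformation / bilinear-transform route, returning
#' transfer-function coefficients.  Matches `scipy.signal.butter(order,
#' c(low, high), btype = "band", fs = fs)`.
#'
#' @param order Prototype (low-pass) order; the result has `2 * order` poles.
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return List with numerator `b` and denominator `a` (both length
#'   `2 * order + 1`, `a[1] == 1`).
#' @export
butter_bandpass <- function(order, low_hz, high_hz, fs) {
  if (high_hz >= fs / 2) stopf("bandpass high edge %g Hz >= Nyquist %g Hz", high_hz, fs / 2)
  if (low_hz <= 0 || low_hz >= high_hz) stopf("need 0 < low < high")
  n <- as.integer(order)
  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # pre-warp edges for the bilinear transform at fs2 = 2*fs
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each pole maps to a conjugate pair
  plp <- p * bw / 2
  pbp <- c(plp + sqrt(plp^2 - w0^2), plp - sqrt(plp^2 - w0^2))
  zbp <- rep(0 + 0i, n)            # n zeros at s = 0
  gain <- bw^n
  # bilinear transform z = (fs2 + s) / (fs2 - s)
  zd <- (fs2 + zbp) / (fs2 - zbp)
  pd <- (fs2 + pbp) / (fs2 - pbp)
  gain <- gain * Re(prod(fs2 - zbp) / prod(fs2 - pbp))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))  # zeros at Nyquist
  b <- Re(gain * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# monic polynomial coefficients from roots, descending powers
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs * root)
  coefs
}

#' Second-order IIR notch filter design
#'
#' Designs the classic biquad notch (matching `scipy.signal.iirnotch`):
#' unit gain away from `f0_hz`, a -Inf dB null at `f0_hz`, and -3 dB points
#' `f0_hz / q` apart.
#'
#' @param f0_hz Centre frequency in Hz.
#' @param q Quality factor.
#' @param fs Sampling rate in Hz.
#' @return List with `b` and `a`, both length 3.
#' @export
iir_notch <- function(f0_hz, q, fs) {
  if (f0_hz >= fs / 2) stopf("notch frequency %g Hz >= Nyquist %g Hz", f0_hz, fs / 2)
  w0 <- 2 * pi * f0_hz / fs
  beta <- tan(w0 / (2 * q))
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * gain * cos(w0), 2 * gain - 1)
  list(b = b, a = a)
}

#' Complex frequency response of a digital filter
#'
#' Evaluates \eqn{H(e^{i 2 \pi f / f_s})} of the rational transfer function
#' `b / a` at the requested frequencies.  Used as the analytic oracle for
#' attenuation/pass-band claims about designed filters.
#'
#' @param b,a Transfer-function coefficients (descending powers of
#'   \eqn{z^{-1}}).
#' @param f_hz Frequencies to evaluate, in Hz.
#' @param fs Sampling rate in Hz.
#' @return Complex vector of the same length as `f_hz`.
#' @export
filter_response <- function(b, a, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  zi <- exp(-1i * outer(w, seq_along(b) - 1))
  num <- drop(zi %*% b)
  zi <- exp(-1i * outer(w, seq_along(a) - 1))
  den <- drop(zi %*% a)
  num / den
}

# Steady-state initial conditions for cpp_lfilter (scipy lfilter_zi):
# the state vector for which a constant input 1 yields a constant output.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  # companion matrix of a, transposed state-update form
  comp <- if (n == 2) matrix(-a[2], 1, 1)
          else rbind(-a[-1], cbind(diag(1, n - 2), 0))
  iminus <- diag(n - 1) - t(comp)
  rhs <- b[-1] - a[-1] * b[1]
  solve(iminus, rhs)
}

# Zero-phase forward-backward filtering with odd-reflection padding,
# matching scipy.signal.filtfilt defaults (padtype "odd",
# padlen = 3 * (max(len(a), len(b)) - 1)).
filtfilt_vec <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  padlen <- 3L * (n - 1L)
  if (length(x) <= padlen)
    stopf("signal length %d too short for filter (needs > %d samples)", length(x), padlen)
  head_ext <- 2 * x[1] - x[seq(padlen + 1, 2)]
  tail_ext <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - padlen)]
  ext <- c(head_ext, x, tail_ext)
  zi <- lfilter_zi(b, a)
  y <- cpp_lfilter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- cpp_lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  y[seq(padlen + 1, padlen + length(x))]
}

#' Apply the notch/band-pass filter chain
#'
#' Applies the filter chain described by a [filter_spec()] to a recording,
#' an epoch set, or a plain numeric matrix, channel by channel.  The notch
#' stage (when present) runs first, then the Butterworth band-pass; both
#' are applied forward-backward (zero phase), so epoch alignment is not
#' shifted by group delay.
#'
#' @param x An `annotated_recording`, an `epoch_set`, or a numeric matrix
#'   (channels x samples).
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz; taken from `x` when it carries one.
#' @return An object of the same shape and class as `x`, filtered.
#' @export
apply_filters <- function(x, spec = filter_spec(), fs = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, "annotated_recording")) {
    x$signal <- apply_filters(x$signal, spec, fs = x$sampling_rate_hz)
    return(x)
  }
  if (inherits(x, "epoch_set")) {
    fs <- x$sampling_rate_hz
    for (i in seq_len(dim(x$epochs)[1]))
      x$epochs[i, , ] <- apply_filters(x$epochs[i, , , drop = TRUE], spec, fs = fs)
    return(x)
  }
  if (is.null(fs)) stopf("fs must be supplied for plain matrices")
  if (spec$bandpass_high_hz >= fs / 2)
    stopf("bandpass high edge %g Hz >= Nyquist %g Hz", spec$bandpass_high_hz, fs / 2)
  x <- as.matrix(x)
  chain <- list()
  if (!is.null(spec$notch_freq_hz))
    chain <- c(chain, list(iir_notch(spec$notch_freq_hz, spec$notch_q, fs)))
  chain <- c(chain, list(butter_bandpass(spec$bandpass_order,
                                         spec$bandpass_low_hz,
                                         spec$bandpass_high_hz, fs)))
  for (filt in chain)
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- filtfilt_vec(filt$b, filt$a, x[ch, ])
  x
}
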