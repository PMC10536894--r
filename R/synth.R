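#' Configuration for the synthetic motor-imagery EEG generator
#'
#' Describes a simulated recording session: geometry (channels, sampling
#' rate, trial count and length), the rhythm band whose event-related
#' desynchronization (ERD) carries the class information, and noise levels.
#' The defaults emulate a desk-scale PhysioNet-style session: 160 Hz, 4 s
#' trials, 45 trials, a mu rhythm at 8--12 Hz, and two classes
#' (left vs. right hand) lateralized over contiguous channel halves.
#'
#' @param n_channels Number of channels (>= 2; class information is carried
#'   by attenuating the rhythm on one contiguous channel block per class).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param n_trials Number of annotated trials.
#' @param trial_duration_s Trial length in seconds;
#'   `trial_duration_s * sampling_rate_hz` must be an integer.
#' @param n_classes Number of classes (>= 2).
#' @param erd_band_hz Length-2 numeric, the rhythm band (low, high) in Hz;
#'   must lie below Nyquist.
#' @param erd_depth Fractional attenuation of the rhythm amplitude on the
#'   class-linked channel block during that class's trials, in \[0, 1\].
#'   0 means no class signal at all.
#' @param noise_std Standard deviation of the additive white noise
#'   (microvolts).
#' @param inter_trial_gap_s Unannotated gap between consecutive trials,
#'   seconds.
#' @param rhythm_amp Baseline amplitude of the band rhythm (microvolts).
#' @param class_labels Optional character vector of class names; defaults to
#'   `c("T1", "T2")` for two classes (PhysioNet annotation codes) and
#'   `"class1" ...` otherwise.
#' @param seed Integer seed; the generated recording is a pure function of
#'   the configuration including this seed.
#' @return An object of class `"synth_config"`.
#' @seealso [simulate_recording()]
#' @export
synth_config <- function(n_channels = 8, sampling_rate_hz = 160, n_trials = 45,
                         trial_duration_s = 4, n_classes = 2,
                         erd_band_hz = c(8, 12), erd_depth = 0.5,
                         noise_std = 1, inter_trial_gap_s = 1,
                         rhythm_amp = 2, class_labels = NULL, seed = 1L) {
  if (!is_count(n_channels) || n_channels < 2)
    stopf("n_channels must be an integer >= 2 (lateralization needs both halves)")
  if (!is_scalar(sampling_rate_hz) || sampling_rate_hz <= 0)
    stopf("sampling_rate_hz must be positive")
  if (!is_count(n_trials)) stopf("n_trials must be a positive integer")
  if (!is_scalar(trial_duration_s) || trial_duration_s <= 0)
    stopf("trial_duration_s must be positive")
  nsamp <- trial_duration_s * sampling_rate_hz
  if (abs(nsamp - round(nsamp)) > 1e-9)
    stopf("trial_duration_s * sampling_rate_hz = %g is not an integer", nsamp)
  if (!is_count(n_classes) || n_classes < 2) stopf("n_classes must be >= 2")
  if (length(erd_band_hz) != 2 || erd_band_hz[1] >= erd_band_hz[2] ||
      erd_band_hz[2] >= sampling_rate_hz / 2)
    stopf("erd_band_hz must satisfy low < high < Nyquist")
  if (!is_scalar(erd_depth) || erd_depth < 0 || erd_depth > 1)
    stopf("erd_depth must be in [0, 1]")
  if (!is_scalar(noise_std) || noise_std < 0) stopf("noise_std must be >= 0")
  if (!is_scalar(inter_trial_gap_s) || inter_trial_gap_s < 0)
    stopf("inter_trial_gap_s must be >= 0")
  if (is.null(class_labels))
    class_labels <- if (n_classes == 2) c("T1", "T2")
                    else sprintf("class%d", seq_len(n_classes))
  if (length(class_labels) != n_classes) stopf("need %d class labels", n_classes)
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate_hz = sampling_rate_hz,
                 n_trials = as.integer(n_trials),
                 trial_duration_s = trial_duration_s,
                 n_classes = as.integer(n_classes),
                 erd_band_hz = as.numeric(erd_band_hz), erd_depth = erd_depth,
                 noise_std = noise_std, inter_trial_gap_s = inter_trial_gap_s,
                 rhythm_amp = rhythm_amp, class_labels = class_labels,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f-shaped ("pink-ish") noise via FFT spectral shaping, unit variance.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index, DC guarded
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Simulate an annotated motor-imagery EEG recording
#'
#' Generates a continuous multi-channel recording of `n_trials` labelled
#' trials separated by unannotated gaps.  Each channel carries 1/f-shaped
#' background noise plus white noise plus a sinusoidal rhythm whose
#' frequency is drawn uniformly from `erd_band_hz` per segment (phase also
#' randomized per segment, so no phase cue is learnable).  During a trial of
#' class *k*, the rhythm amplitude on the *k*-th contiguous channel block is
#' attenuated by `erd_depth` — the event-related desynchronization that a
#' classifier can pick up.  Class labels are drawn uniformly.  The output is
#' a pure function of the configuration (including its seed).
#'
#' @param config A [synth_config()].
#' @return An [annotated_recording()] whose events exactly delimit the
#'   trials.
#' @examples
#' rec <- simulate_recording(synth_config(n_trials = 5, seed = 42))
#' rec
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate_hz
  trial_len <- as.integer(round(config$trial_duration_s * fs))
  gap_len <- as.integer(round(config$inter_trial_gap_s * fs))
  total <- config$n_trials * (trial_len + gap_len)
  C <- config$n_channels
  K <- config$n_classes
  # contiguous channel blocks, class k linked to block k (round robin for
  # channels beyond an even split)
  block <- rep(seq_len(K), each = ceiling(C / K), length.out = C)

  with_seed(config$seed, {
    labels <- sample.int(K, config$n_trials, replace = TRUE)
    signal <- matrix(0, C, total)
    for (ch in seq_len(C))
      signal[ch, ] <- pink_noise(total) +
        stats::rnorm(total, sd = config$noise_std)
    onsets <- (seq_len(config$n_trials) - 1L) * (trial_len + gap_len)
    t_trial <- seq_len(trial_len) / fs
    t_gap <- if (gap_len > 0) seq_len(gap_len) / fs else numeric(0)
    for (i in seq_len(config$n_trials)) {
      for (ch in seq_len(C)) {
        amp <- config$rhythm_amp
        if (block[ch] == labels[i]) amp <- amp * (1 - config$erd_depth)
        f0 <- stats::runif(1, config$erd_band_hz[1], config$erd_band_hz[2])
        ph <- stats::runif(1, 0, 2 * pi)
        idx <- onsets[i] + seq_len(trial_len)
        signal[ch, idx] <- signal[ch, idx] + amp * sin(2 * pi * f0 * t_trial + ph)
        if (gap_len > 0) {
          f0 <- stats::runif(1, config$erd_band_hz[1], config$erd_band_hz[2])
          ph <- stats::runif(1, 0, 2 * pi)
          idx <- onsets[i] + trial_len + seq_len(gap_len)
          signal[ch, idx] <- signal[ch, idx] +
            config$rhythm_amp * sin(2 * pi * f0 * t_gap + ph)
        }
      }
    }
    events <- data.frame(onset_sample = onsets,
                         duration_samples = trial_len,
                         label = config$class_labels[labels],
                         stringsAsFactors = FALSE)
    annotated_recording(signal, fs, events)
  })
}

#' Band power of a signal segment via the periodogram
#'
#' Sums `|FFT|^2 / n` over the bins falling inside `band_hz`.  This is the
#' brute-force statistic used to verify that the synthetic generator's
#' class-dependent desynchronization is really present.
#'
#' @param x Numeric vector (one channel segment).
#' @param fs Sampling rate in Hz.
#' @param band_hz Length-2 band (low, high), inclusive.
#' @return Scalar band power.
#' @export
bandpower <- function(x, fs, band_hz) {
  n <- length(x)
  p <- abs(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= band_hz[1] & f <= band_hz[2]])
}
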