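#' Annotated multi-channel EEG recording
#'
#' The package's continuous-signal container: a channels x samples matrix in
#' microvolts, a sampling rate, channel names, and a table of labelled event
#' intervals.  Events use 0-based sample indices and half-open
#' `[onset, onset + duration)` intervals, must be sorted by onset, and must
#' not overlap.
#'
#' @param signal Numeric matrix, channels x samples (microvolts).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param events `data.frame` with columns `onset_sample` (integer, 0-based),
#'   `duration_samples` (integer) and `label` (character).
#' @param channel_names Character vector, one name per channel.
#' @return An object of class `"annotated_recording"`.
#' @export
annotated_recording <- function(signal, sampling_rate_hz, events = NULL,
                                channel_names = NULL) {
  signal <- as.matrix(signal)
  if (!is_scalar(sampling_rate_hz) || sampling_rate_hz <= 0)
    stopf("sampling_rate_hz must be a positive number")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stopf("channel_names length %d != %d channels", length(channel_names), nrow(signal))
  if (is.null(events))
    events <- data.frame(onset_sample = integer(), duration_samples = integer(),
                         label = character(), stringsAsFactors = FALSE)
  events <- as.data.frame(events)
  need <- c("onset_sample", "duration_samples", "label")
  if (!all(need %in% names(events)))
    stopf("events must have columns %s", paste(need, collapse = ", "))
  events$onset_sample <- as.integer(events$onset_sample)
  events$duration_samples <- as.integer(events$duration_samples)
  events$label <- as.character(events$label)
  if (nrow(events)) {
    if (is.unsorted(events$onset_sample))
      stopf("events must be sorted by onset")
    ends <- events$onset_sample + events$duration_samples
    if (any(events$onset_sample < 0) || any(ends > ncol(signal)))
      stopf("event intervals must lie within [0, n_samples)")
    if (any(events$onset_sample[-1] < ends[-nrow(events)]))
      stopf("events must not overlap")
  }
  structure(list(signal = signal, sampling_rate_hz = sampling_rate_hz,
                 channel_names = channel_names, events = events),
            class = "annotated_recording")
}

#' @export
print.annotated_recording <- function(x, ...) {
  cat(sprintf("<annotated_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate_hz,
              ncol(x$signal) / x$sampling_rate_hz))
  if (nrow(x$events)) {
    tab <- table(x$events$label)
    cat(sprintf("  %d events: %s\n", nrow(x$events),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  } else cat("  no events\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$signal)
n_channels <- function(rec) nrow(rec$signal)
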