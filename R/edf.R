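# Minimal EDF+C writer/reader: 16-bit samples, physical units microvolts,
# one "EDF Annotations" signal carrying the event list as time-stamped
# annotation lists (TALs).  Covers what this package emits; it is not a
# general-purpose EDF library (no discontinuous files, no per-signal
# sampling rates on read beyond what was written).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- vapply(x, function(v) {
    out <- formatC(v, format = "fg", width = 1, digits = 10)
    if (nchar(out) > width) out <- substr(out, 1, width)
    out
  }, "")
  edf_pad(s, width)
}

#' Write an annotated recording to an EDF+ file
#'
#' Serializes the recording as EDF+C: each signal quantized to 16 bits over
#' a symmetric physical range covering its amplitude, events stored in an
#' "EDF Annotations" signal (onset/duration in seconds).  Data records are
#' 1 s long when the recording length is a whole number of seconds;
#' otherwise a single record spanning the recording is written.
#'
#' @param rec An [annotated_recording()].
#' @param path Output file path.
#' @param physical_max Symmetric physical range bound in microvolts;
#'   defaults to the smallest power of ten covering the signal.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path, physical_max = NULL) {
  stopifnot(inherits(rec, "annotated_recording"))
  C <- n_channels(rec); N <- n_samples(rec); fs <- rec$sampling_rate_hz
  if (C > 255) stopf("EDF supports at most 255 signals (+1 annotation signal)")
  amax <- max(abs(rec$signal), 1e-12)
  if (is.null(physical_max)) physical_max <- 10^ceiling(log10(amax * 1.001))
  if (amax > physical_max)
    stopf("signal amplitude %.3g exceeds physical range %.3g", amax, physical_max)

  whole_seconds <- abs(N / fs - round(N / fs)) < 1e-9 && fs == round(fs)
  if (whole_seconds) {
    n_rec <- as.integer(round(N / fs)); rec_dur <- 1; spr <- as.integer(fs)
  } else {
    n_rec <- 1L; rec_dur <- N / fs; spr <- N
  }

  # digital quantization: physical [-pm, pm] <-> digital [-32767, 32767]
  dig <- round(rec$signal / physical_max * 32767)
  storage.mode(dig) <- "integer"

  # one TAL block per record: the mandatory timestamp, then events whose
  # onset falls inside the record
  ev <- rec$events
  ev_on <- ev$onset_sample / fs
  ev_dur <- ev$duration_samples / fs
  tal_blocks <- character(n_rec)
  for (r in seq_len(n_rec)) {
    t0 <- (r - 1) * rec_dur
    tal <- sprintf("+%s\x14\x14", format(t0, trim = TRUE, scientific = FALSE))
    inside <- which(ev_on >= t0 - 1e-9 & ev_on < t0 + rec_dur - 1e-9)
    for (j in inside)
      tal <- paste0(tal, sprintf("+%.7f\x15%.7f\x14%s\x14",
                                 ev_on[j], ev_dur[j], ev$label[j]))
    tal_blocks[r] <- tal  # nul terminator appended at the raw level on write
  }
  ann_bytes <- max(nchar(tal_blocks, type = "bytes")) + 1L
  ann_spr <- as.integer(ceiling(ann_bytes / 2) + 1)  # int16 samples, slack

  ns <- C + 1L
  header <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),                    # local patient id (anonymous)
    edf_pad("Startdate X X X X", 80),          # local recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(256 * (ns + 1)), 8),
    edf_pad("EDF+C", 44),
    edf_pad(as.character(n_rec), 8),
    edf_num(rec_dur, 8),
    edf_pad(as.character(ns), 4),
    paste(edf_pad(c(rec$channel_names, "EDF Annotations"), 16), collapse = ""),
    paste(edf_pad(c(rep("AgAgCl electrode", C), ""), 80), collapse = ""),
    paste(edf_pad(c(rep("uV", C), ""), 8), collapse = ""),
    paste(edf_num(c(rep(-physical_max, C), -1), 8), collapse = ""),
    paste(edf_num(c(rep(physical_max, C), 1), 8), collapse = ""),
    paste(edf_num(c(rep(-32767, C), -32768), 8), collapse = ""),
    paste(edf_num(c(rep(32767, C), 32767), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),   # prefiltering
    paste(edf_pad(c(rep(spr, C), ann_spr), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 32), collapse = "")    # reserved
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  for (r in seq_len(n_rec)) {
    idx0 <- (r - 1) * spr
    take <- min(spr, N - idx0)
    for (ch in seq_len(C)) {
      seg <- integer(spr)
      if (take > 0) seg[seq_len(take)] <- dig[ch, idx0 + seq_len(take)]
      writeBin(seg, con, size = 2, endian = "little")
    }
    tal_raw <- c(charToRaw(tal_blocks[r]), as.raw(0))
    buf <- raw(2 * ann_spr)
    buf[seq_along(tal_raw)] <- tal_raw
    writeBin(buf, con)
  }
  invisible(path)
}

#' Read an EDF+ file written by this package
#'
#' Parses the header, rescales the 16-bit samples to physical units, and
#' decodes the annotation signal's TALs back into an event table (0-based
#' sample indices).  The timekeeping annotations that merely stamp each
#' data record are dropped.
#'
#' @param path Path to an EDF/EDF+ file.
#' @return An [annotated_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rd(8 + 80 + 80 + 8 + 8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  fs <- spr[sig_idx[1]] / rec_dur
  chunks <- vector("list", n_rec)
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    mat <- matrix(0, length(sig_idx), spr[sig_idx[1]])
    row <- 0L
    for (s in seq_len(ns)) {
      if (is_ann[s]) {
        bytes <- readBin(con, "raw", 2 * spr[s])
        ann_text <- c(ann_text, rawToChar(bytes[bytes != as.raw(0)]))
      } else {
        row <- row + 1L
        v <- readBin(con, "integer", spr[s], size = 2, endian = "little")
        scale <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
        mat[row, ] <- pmin_[s] + (v - dmin_[s]) * scale
      }
    }
    chunks[[r]] <- mat
  }
  signal <- do.call(cbind, chunks)

  # decode TALs: fields split by \x14, onset[\x15 duration] prefix
  tals <- strsplit(paste(ann_text, collapse = ""), "\x14\\+", perl = TRUE)[[1]]
  events <- list()
  for (tal in tals) {
    tal <- sub("^\\+", "", tal)
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(trimws(parts[2]))) next  # timestamp TAL
    od <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- as.numeric(od[1])
    dur <- if (length(od) > 1) as.numeric(od[2]) else 0
    events[[length(events) + 1]] <-
      data.frame(onset_sample = as.integer(round(onset * fs)),
                 duration_samples = as.integer(round(dur * fs)),
                 label = parts[2], stringsAsFactors = FALSE)
  }
  events <- if (length(events)) do.call(rbind, events) else NULL
  if (!is.null(events)) events <- events[order(events$onset_sample), , drop = FALSE]
  annotated_recording(signal, fs, events, channel_names = labels[sig_idx])
}
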