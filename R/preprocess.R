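#' Drop subjects with unreliable annotations
#'
#' The PhysioNet motor movement/imagery corpus has six subjects whose runs
#' are mis-annotated; standard practice is to exclude them, leaving 103 of
#' the 109 subjects.  IDs not present in the input are ignored.
#'
#' @param subject_ids Integer vector of candidate subject IDs.
#' @param excluded Integer vector of IDs to drop.
#' @return `subject_ids` minus `excluded`, order preserved.
#' @examples
#' length(exclude_subjects(1:109))  # 103
#' @export
exclude_subjects <- function(subject_ids, excluded = c(38, 88, 89, 82, 100, 104)) {
  subject_ids[!(subject_ids %in% excluded)]
}

#' Extract fixed-length labelled epochs from a recording
#'
#' Cuts one epoch per event whose label is in `keep_labels`, starting
#' `offset_s` after the event onset and lasting `epoch_duration_s`.  Events
#' too close to the end of the recording to yield a full epoch are dropped
#' (a message reports how many).  Rest-period annotations are excluded
#' simply by leaving their label out of `keep_labels`.
#'
#' @param rec An [annotated_recording()].
#' @param keep_labels Character vector of event labels to epoch.
#' @param epoch_duration_s Epoch length in seconds; times sampling rate must
#'   be an integer.
#' @param offset_s Start offset from the event onset in seconds (e.g. 1.5 s
#'   for the BCI IV-2a cue-to-imagery delay).
#' @return An object of class `"epoch_set"`: list with `epochs` (array
#'   n_epochs x channels x samples), `labels` (integer, 1-based index into
#'   `class_names`), `class_names` (= `keep_labels`) and `sampling_rate_hz`.
#' @export
extract_epochs <- function(rec, keep_labels, epoch_duration_s, offset_s = 0) {
  stopifnot(inherits(rec, "annotated_recording"))
  fs <- rec$sampling_rate_hz
  wlen <- epoch_duration_s * fs
  if (!is_scalar(epoch_duration_s) || epoch_duration_s <= 0)
    stopf("epoch_duration_s must be positive")
  if (abs(wlen - round(wlen)) > 1e-9)
    stopf("epoch_duration_s * sampling rate = %g is not an integer", wlen)
  wlen <- as.integer(round(wlen))
  off <- as.integer(round(offset_s * fs))
  ev <- rec$events[rec$events$label %in% keep_labels, , drop = FALSE]
  if (!nrow(ev)) stopf("no events with labels %s", paste(keep_labels, collapse = ", "))
  starts <- ev$onset_sample + off
  ok <- starts >= 0 & (starts + wlen) <= n_samples(rec)
  if (any(!ok))
    message(sprintf("dropping %d event(s) too close to the record edge", sum(!ok)))
  ev <- ev[ok, , drop = FALSE]; starts <- starts[ok]
  if (!nrow(ev)) stopf("no events leave room for a full epoch")
  epochs <- array(0, c(nrow(ev), n_channels(rec), wlen))
  for (i in seq_len(nrow(ev)))
    epochs[i, , ] <- rec$signal[, starts[i] + seq_len(wlen), drop = FALSE]
  structure(list(epochs = epochs,
                 labels = match(ev$label, keep_labels),
                 class_names = keep_labels,
                 sampling_rate_hz = fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate_hz))
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Partition epochs into non-overlapping labelled windows
#'
#' Splits every epoch into consecutive, non-overlapping windows of
#' `window_len` samples (stride = length, i.e. a partition); each window
#' inherits its source epoch's label.  A trailing remainder shorter than
#' `window_len` is dropped (a message reports the per-epoch remainder).
#' Concatenating one epoch's windows in order reconstructs the epoch
#' (minus any remainder).
#'
#' @param epochs An `epoch_set` from [extract_epochs()].
#' @param window_len Window length in samples.
#' @return An object of class `"windowed_dataset"`: list with `windows`
#'   (array n_windows x channels x window_len), `labels`, `class_names`,
#'   `sampling_rate_hz`, and `provenance` (data.frame `epoch`, `window`).
#' @examples
#' \dontrun{
#' ws <- window_epochs(ep, 80)  # 640-sample epochs -> 8 windows each
#' }
#' @export
window_epochs <- function(epochs, window_len) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  if (!is_count(window_len)) stopf("window_len must be a positive integer")
  window_len <- as.integer(window_len)
  if (window_len > d[3])
    stopf("window_len %d exceeds epoch length %d", window_len, d[3])
  per <- d[3] %/% window_len
  rem <- d[3] %% window_len
  if (rem > 0)
    message(sprintf("dropping %d trailing sample(s) per epoch", rem))
  nw <- d[1] * per
  windows <- array(0, c(nw, d[2], window_len))
  prov <- data.frame(epoch = integer(nw), window = integer(nw))
  labels <- integer(nw)
  r <- 0L
  for (i in seq_len(d[1])) {
    for (w in seq_len(per)) {
      r <- r + 1L
      windows[r, , ] <- epochs$epochs[i, , (w - 1L) * window_len + seq_len(window_len)]
      prov$epoch[r] <- i; prov$window[r] <- w
      labels[r] <- epochs$labels[i]
    }
  }
  structure(list(windows = windows, labels = labels,
                 class_names = epochs$class_names,
                 sampling_rate_hz = epochs$sampling_rate_hz,
                 provenance = prov),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<windowed_dataset> %d windows x %d channels x %d samples\n",
              d[1], d[2], d[3]))
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# rbind two windowed datasets (used by session splits and multi-subject runs)
combine_windows <- function(a, b) {
  stopifnot(identical(a$class_names, b$class_names),
            identical(dim(a$windows)[-1], dim(b$windows)[-1]))
  da <- dim(a$windows)[1]
  windows <- array(0, c(da + dim(b$windows)[1], dim(a$windows)[2], dim(a$windows)[3]))
  windows[seq_len(da), , ] <- a$windows
  windows[da + seq_len(dim(b$windows)[1]), , ] <- b$windows
  structure(list(windows = windows, labels = c(a$labels, b$labels),
                 class_names = a$class_names,
                 sampling_rate_hz = a$sampling_rate_hz,
                 provenance = rbind(a$provenance, b$provenance)),
            class = "windowed_dataset")
}

# subset a windowed dataset by window index
subset_windows <- function(x, idx) {
  structure(list(windows = x$windows[idx, , , drop = FALSE],
                 labels = x$labels[idx],
                 class_names = x$class_names,
                 sampling_rate_hz = x$sampling_rate_hz,
                 provenance = x$provenance[idx, , drop = FALSE]),
            class = "windowed_dataset")
}

#' Per-channel z-scoring with training-set statistics
#'
#' Computes a per-channel mean and standard deviation on the training
#' windows only, then applies the same affine transform to the training set
#' and to any number of held-out sets — the standardization used for the
#' BCI IV-2a/2b recipes.  Statistics are returned for audit.
#'
#' @param train A `windowed_dataset` (or plain array n x C x W) defining the
#'   statistics.
#' @param ... Further datasets/arrays standardized with the training
#'   statistics.
#' @return List with `train`, `others` (list), and `stats` (data.frame
#'   `channel`, `mean`, `sd`).
#' @export
standardize <- function(train, ...) {
  others <- list(...)
  arr <- function(x) if (inherits(x, "windowed_dataset")) x$windows else x
  xt <- arr(train)
  if (!length(xt) || dim(xt)[1] == 0) stopf("training set is empty")
  C <- dim(xt)[2]
  mu <- numeric(C); sdv <- numeric(C)
  for (ch in seq_len(C)) {
    v <- xt[, ch, ]
    mu[ch] <- mean(v)
    sdv[ch] <- stats::sd(as.vector(v))
    if (!is.finite(sdv[ch]) || sdv[ch] <= 0)
      stopf("channel %d has zero variance in the training set", ch)
  }
  apply_stats <- function(x) {
    a <- arr(x)
    for (ch in seq_len(C)) a[, ch, ] <- (a[, ch, ] - mu[ch]) / sdv[ch]
    if (inherits(x, "windowed_dataset")) { x$windows <- a; x } else a
  }
  list(train = apply_stats(train),
       others = lapply(others, apply_stats),
       stats = data.frame(channel = seq_len(C), mean = mu, sd = sdv))
}

#' Dataset preprocessing recipes
#'
#' Bundled parameter sets reproducing the three dataset pipelines:
#' `"eegmmidb"` (notch 60 Hz + Butterworth 2--60 Hz order 5 on the
#' continuous signal, 4 s epochs at the annotation onset, eight 80-sample
#' windows per epoch), `"bci2a"` (4.5 s epochs offset 1.5 s after the cue,
#' 1125 samples at 250 Hz, standardization, whole-epoch windows) and
#' `"bci2b"` (as 2a but 2-class, 3 channels).
#'
#' @param name One of `"eegmmidb"`, `"bci2a"`, `"bci2b"`.
#' @return List of recipe parameters (`filter`, `keep_labels`,
#'   `epoch_duration_s`, `offset_s`, `window_len`, `standardize`).
#' @export
preprocess_recipe <- function(name = c("eegmmidb", "bci2a", "bci2b")) {
  name <- match.arg(name)
  switch(name,
    eegmmidb = list(name = name, filter = filter_spec(),
                    keep_labels = c("T1", "T2"),
                    epoch_duration_s = 4, offset_s = 0, window_len = 80L,
                    standardize = FALSE),
    bci2a = list(name = name, filter = NULL,
                 keep_labels = c("left", "right", "feet", "tongue"),
                 epoch_duration_s = 4.5, offset_s = 1.5, window_len = 1125L,
                 standardize = TRUE),
    bci2b = list(name = name, filter = NULL,
                 keep_labels = c("left", "right"),
                 epoch_duration_s = 4.5, offset_s = 1.5, window_len = 1125L,
                 standardize = TRUE))
}

#' Run a preprocessing recipe on one recording
#'
#' Filters the continuous recording (before epoching, so filter transients
#' fall outside the windows), extracts epochs and windows them, per the
#' named recipe.  Standardization for session-split recipes is applied
#' later, at split time, with training-set statistics (see
#' [standardize()]).
#'
#' @param rec An [annotated_recording()].
#' @param recipe A recipe list from [preprocess_recipe()], or a name.
#' @param keep_labels Optional override of the recipe's event labels (the
#'   synthetic generator's labels, for instance).
#' @return A `windowed_dataset`.
#' @export
preprocess_recording <- function(rec, recipe = "eegmmidb", keep_labels = NULL) {
  if (is.character(recipe)) recipe <- preprocess_recipe(recipe)
  if (!is.null(recipe$filter)) rec <- apply_filters(rec, recipe$filter)
  keep <- keep_labels %||% recipe$keep_labels
  ep <- extract_epochs(rec, keep, recipe$epoch_duration_s, recipe$offset_s)
  window_epochs(ep, recipe$window_len)
}

#' Persist / load a windowed dataset as delimited text plus manifest
#'
#' Writes `windows.csv` (one row per window, channels-major flattening),
#' `labels.csv`, and `manifest.json` (shapes, class names, sampling rate)
#' into a directory, and reads them back.
#'
#' @param x A `windowed_dataset`.
#' @param dir Directory to create/use.
#' @return `write_windows`: `dir`, invisibly.  `read_windows`: the
#'   `windowed_dataset`.
#' @export
write_windows <- function(x, dir) {
  stopifnot(inherits(x, "windowed_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(x$windows)
  flat <- matrix(x$windows, nrow = d[1])  # column index = (w-1)*C + c
  utils::write.table(round(flat, 6), file.path(dir, "windows.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(label = x$labels,
                                epoch = x$provenance$epoch,
                                window = x$provenance$window),
                     file.path(dir, "labels.csv"),
                     sep = ",", row.names = FALSE)
  jsonlite::write_json(list(n_windows = d[1], n_channels = d[2],
                            window_len = d[3],
                            class_names = x$class_names,
                            sampling_rate_hz = x$sampling_rate_hz,
                            fingerprint = object_hash(round(x$windows, 6))),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_windows
#' @export
read_windows <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "windows.csv"), sep = ","))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  windows <- array(as.numeric(flat),
                   c(man$n_windows, man$n_channels, man$window_len))
  structure(list(windows = windows, labels = as.integer(lab$label),
                 class_names = man$class_names,
                 sampling_rate_hz = man$sampling_rate_hz,
                 provenance = data.frame(epoch = lab$epoch, window = lab$window)),
            class = "windowed_dataset")
}
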