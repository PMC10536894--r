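#' Annotation sidecar files for non-EDF recordings
#'
#' A recording whose signal arrives outside EDF (a plain numeric matrix,
#' another format's export) can carry its events in a delimited-text
#' sidecar with header `onset_sample`, `duration_samples`, `label` —
#' 0-based sample indices, tab-separated.  `read_annotations()` parses such
#' a file into the event table accepted by [annotated_recording()];
#' `write_annotations()` writes one.
#'
#' @param path Sidecar file path.
#' @param events Event `data.frame` (or an `annotated_recording`, whose
#'   events are taken).
#' @return `read_annotations`: the events `data.frame`.
#'   `write_annotations`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_annotations(data.frame(onset_sample = 0L, duration_samples = 640L,
#'                              label = "T1"), f)
#' read_annotations(f)
#' @export
read_annotations <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_sample", "duration_samples", "label")
  if (!all(need %in% names(ev)))
    stopf("sidecar must have columns %s", paste(need, collapse = ", "))
  ev$onset_sample <- as.integer(ev$onset_sample)
  ev$duration_samples <- as.integer(ev$duration_samples)
  ev$label <- as.character(ev$label)
  ev[need]
}

#' @rdname read_annotations
#' @export
write_annotations <- function(events, path) {
  if (inherits(events, "annotated_recording")) events <- events$events
  utils::write.table(events[c("onset_sample", "duration_samples", "label")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
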