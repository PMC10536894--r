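#' Hyperparameters of one convolutional branch
#'
#' One branch follows the EEGNet layout: a temporal convolution (a learned
#' frequency filter bank), a depthwise spatial convolution across all
#' channels, and a separable temporal convolution, with batch
#' normalization, ELU activations, average pooling and dropout in between.
#'
#' @param n_temporal_filters Number of temporal convolution filters (F1).
#' @param temporal_kernel_len Length of each 1 x k temporal kernel.
#' @param n_separable_filters Number of pointwise output filters of the
#'   separable convolution (F2).
#' @param separable_kernel_len Length of the separable depthwise kernel.
#' @param depth_multiplier Spatial filters learned per temporal filter (D).
#' @param pool1_len,pool2_len Average-pooling lengths after the depthwise
#'   and separable stages.
#' @param dropout_p Dropout probability after each pooling stage.
#' @return An object of class `"branch_spec"`.
#' @export
branch_spec <- function(n_temporal_filters, temporal_kernel_len,
                        n_separable_filters, separable_kernel_len,
                        depth_multiplier = 2L, pool1_len = 4L, pool2_len = 8L,
                        dropout_p = 0.5) {
  for (nm in c("n_temporal_filters", "temporal_kernel_len",
               "n_separable_filters", "separable_kernel_len",
               "depth_multiplier", "pool1_len", "pool2_len")) {
    v <- get(nm)
    if (!is_count(v)) stopf("%s must be a positive integer", nm)
  }
  if (!is_scalar(dropout_p) || dropout_p < 0 || dropout_p >= 1)
    stopf("dropout_p must be in [0, 1)")
  structure(list(n_temporal_filters = as.integer(n_temporal_filters),
                 temporal_kernel_len = as.integer(temporal_kernel_len),
                 n_separable_filters = as.integer(n_separable_filters),
                 separable_kernel_len = as.integer(separable_kernel_len),
                 depth_multiplier = as.integer(depth_multiplier),
                 pool1_len = as.integer(pool1_len),
                 pool2_len = as.integer(pool2_len),
                 dropout_p = dropout_p),
            class = "branch_spec")
}

#' Full multi-branch fusion network specification
#'
#' All branches receive the identical (channels x window) input; their
#' flattened feature maps are concatenated in a fusion layer feeding a
#' softmax classification head.
#'
#' @param branches List of [branch_spec()] objects (>= 1).
#' @param n_channels Input channel count C.
#' @param window_len Input window length W (samples).
#' @param n_classes Number of output classes (>= 2).
#' @return An object of class `"fusion_model_spec"`.
#' @export
fusion_model_spec <- function(branches, n_channels, window_len, n_classes) {
  if (!length(branches)) stopf("need at least one branch")
  ok <- vapply(branches, inherits, TRUE, what = "branch_spec")
  if (!all(ok)) stopf("branches must all be branch_spec objects")
  if (!is_count(n_channels)) stopf("n_channels must be a positive integer")
  if (!is_count(window_len)) stopf("window_len must be a positive integer")
  if (!is_count(n_classes) || n_classes < 2) stopf("n_classes must be >= 2")
  for (b in branches) {
    t2 <- (window_len %/% b$pool1_len) %/% b$pool2_len
    if (t2 < 1)
      stopf("window_len %d leaves no time steps after pooling %d x %d",
            window_len, b$pool1_len, b$pool2_len)
  }
  structure(list(branches = branches, n_channels = as.integer(n_channels),
                 window_len = as.integer(window_len),
                 n_classes = as.integer(n_classes)),
            class = "fusion_model_spec")
}

#' @export
print.fusion_model_spec <- function(x, ...) {
  cat(sprintf("<fusion_model_spec> %d branches, input %d x %d, %d classes\n",
              length(x$branches), x$n_channels, x$window_len, x$n_classes))
  for (i in seq_along(x$branches)) {
    b <- x$branches[[i]]
    cat(sprintf("  branch %d: %d temporal filters (1 x %d), D=%d, %d separable filters (1 x %d), pool %d/%d\n",
                i, b$n_temporal_filters, b$temporal_kernel_len,
                b$depth_multiplier, b$n_separable_filters,
                b$separable_kernel_len, b$pool1_len, b$pool2_len))
  }
  invisible(x)
}

# the five branches' published hyperparameters; only the temporal kernel
# lengths vary across the filter-size ablation tests
v2_temporal_filters <- c(8L, 16L, 32L, 64L, 128L)
v2_separable_filters <- c(16L, 32L, 64L, 128L, 256L)
v2_separable_kernels <- c(8L, 16L, 32L, 64L, 128L)
v2_kernel_tests <- list(
  `1` = c(64L, 128L, 256L, 512L, 1024L),
  `2` = c(64L, 256L, 544L, 512L, 1024L),
  `3` = c(64L, 304L, 544L, 784L, 1024L),
  `4` = c(64L, 80L, 96L, 112L, 128L),
  `5` = c(64L, 96L, 128L, 192L, 256L))

#' The default five-branch fusion specification
#'
#' Returns the published five-branch configuration (the filter-size
#' ablation's "Test 4", chosen for its accuracy/compute balance): temporal
#' filter counts 8/16/32/64/128 with kernel lengths 64/80/96/112/128,
#' separable filter counts 16/32/64/128/256 with kernel lengths
#' 8/16/32/64/128, dropout 0.5 throughout.  Depth multiplier 2 and pooling
#' 4/8 follow the EEGNet defaults (unstated in the source architecture and
#' configurable per branch).
#'
#' @param n_channels,window_len,n_classes Input geometry and class count.
#' @param dropout_p Dropout probability (0.5 by default).
#' @return A [fusion_model_spec()] with five branches.
#' @export
default_v2_spec <- function(n_channels, window_len, n_classes = 2,
                            dropout_p = 0.5) {
  test_config_spec(4L, n_channels, window_len, n_classes, dropout_p)
}

#' Filter-size ablation specifications (Tests 1--5)
#'
#' The five-branch specification with the temporal kernel lengths of the
#' named ablation test; everything else matches [default_v2_spec()]
#' (Test 4 *is* the default configuration).
#'
#' @param test_id Integer 1..5.
#' @inheritParams default_v2_spec
#' @return A [fusion_model_spec()].
#' @export
test_config_spec <- function(test_id, n_channels, window_len, n_classes = 2,
                             dropout_p = 0.5) {
  key <- as.character(test_id)
  if (!key %in% names(v2_kernel_tests)) stopf("unknown test_id %s", key)
  kl <- v2_kernel_tests[[key]]
  branches <- lapply(1:5, function(i)
    branch_spec(v2_temporal_filters[i], kl[i],
                v2_separable_filters[i], v2_separable_kernels[i],
                dropout_p = dropout_p))
  fusion_model_spec(branches, n_channels, window_len, n_classes)
}

#' Serialize / deserialize a fusion specification as JSON
#'
#' @param spec A [fusion_model_spec()].
#' @param path File path.
#' @return `write_model_spec`: `path` invisibly; `read_model_spec`: the
#'   spec.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "fusion_model_spec"))
  jsonlite::write_json(list(n_channels = spec$n_channels,
                            window_len = spec$window_len,
                            n_classes = spec$n_classes,
                            branches = lapply(spec$branches, unclass)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  branches <- lapply(seq_len(nrow(x$branches)), function(i)
    do.call(branch_spec, as.list(x$branches[i, ])))
  fusion_model_spec(branches, x$n_channels, x$window_len, x$n_classes)
}
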