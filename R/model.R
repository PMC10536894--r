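#' Build an untrained fusion network from its specification
#'
#' Instantiates the network (Glorot-uniform weights, unit batch-norm) and
#' computes its structural bookkeeping: per-branch feature dimensions after
#' both pooling stages, the fused feature dimension, and the trainable
#' parameter count.
#'
#' @param spec A [fusion_model_spec()].
#' @param seed Integer seed for weight initialization (`NULL` uses the
#'   ambient RNG state).
#' @return An object of class `"fusion_model"` with elements `spec`, `net`
#'   (weights and batch-norm state) and `summary` (a `model_summary`).
#' @examples
#' m <- build_model(default_v2_spec(n_channels = 8, window_len = 80), seed = 1)
#' summary(m)
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "fusion_model_spec"))
  net <- with_seed(seed, init_net(spec))
  dims <- branch_feature_dims(spec)
  summ <- structure(list(per_branch_feature_dims = dims,
                         fused_dim = sum(dims),
                         trainable_parameter_count = count_params(net),
                         n_branches = length(spec$branches)),
                    class = "model_summary")
  structure(list(spec = spec, net = net, summary = summ),
            class = "fusion_model")
}

#' @export
print.model_summary <- function(x, ...) {
  cat("<model_summary>\n")
  cat(sprintf("  branches: %d\n", x$n_branches))
  cat(sprintf("  per-branch feature dims: %s\n",
              paste(x$per_branch_feature_dims, collapse = ", ")))
  cat(sprintf("  fused feature dim: %d\n", x$fused_dim))
  cat(sprintf("  trainable parameters: %s\n",
              format(x$trainable_parameter_count, big.mark = ",")))
  invisible(x)
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %d branches, input %d x %d, %d classes, %s parameters\n",
              length(x$spec$branches), x$spec$n_channels, x$spec$window_len,
              x$spec$n_classes,
              format(x$summary$trainable_parameter_count, big.mark = ",")))
  invisible(x)
}

#' @export
summary.fusion_model <- function(object, ...) object$summary

#' Model structural summary
#'
#' @param model A `fusion_model` (or fitted `eegnet_fusion`).
#' @return The `model_summary`: per-branch feature dimensions, fused
#'   dimension and trainable parameter count.
#' @export
model_summary <- function(model) {
  if (inherits(model, "eegnet_fusion")) return(model$model$summary)
  stopifnot(inherits(model, "fusion_model"))
  model$summary
}

#' @export
predict.fusion_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "windowed_dataset")) newdata$windows else newdata
  probs <- net_forward(object$net, x, train = FALSE, keep_cache = FALSE)$probs
  colnames(probs) <- attr(object, "class_names") %||%
    sprintf("class%d", seq_len(ncol(probs)))
  if (type == "prob") probs
  else max.col(probs, ties.method = "first")
}
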