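#' Training configuration
#'
#' Optimization settings reproducing the published protocol: Adam with
#' learning rate 1e-5, cross-entropy loss (binary for two-class tasks,
#' categorical otherwise), a seed-fixed random 70/10/20
#' train/validation/test split, and checkpointing of the weights with the
#' best validation accuracy.  Batch size and epoch count are not stated in
#' the source protocol; the defaults (16, 100) are configurable.
#'
#' @param learning_rate Adam learning rate.
#' @param loss `"binary"`, `"categorical"`, or `"auto"` (binary for 2
#'   classes, categorical otherwise).
#' @param batch_size Minibatch size.
#' @param max_epochs Number of training epochs.
#' @param split_fractions Length-3 numeric (train, validation, test)
#'   summing to 1.
#' @param seed Integer seed governing the split, weight initialization,
#'   shuffling and dropout.
#' @param checkpoint_dir Optional directory for on-disk weight checkpoints;
#'   by default the best weights are kept in memory only.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-5,
                         loss = c("auto", "binary", "categorical"),
                         batch_size = 16, max_epochs = 100,
                         split_fractions = c(0.7, 0.1, 0.2), seed = 1L,
                         checkpoint_dir = NULL) {
  loss <- match.arg(loss)
  if (!is_scalar(learning_rate) || learning_rate <= 0)
    stopf("learning_rate must be positive")
  if (!is_count(batch_size)) stopf("batch_size must be a positive integer")
  if (!is.numeric(max_epochs) || max_epochs < 0 || max_epochs != floor(max_epochs))
    stopf("max_epochs must be a nonnegative integer")
  if (length(split_fractions) != 3 || any(split_fractions < 0) ||
      abs(sum(split_fractions) - 1) > 1e-9)
    stopf("split_fractions must be three nonnegative numbers summing to 1")
  structure(list(learning_rate = learning_rate, loss = loss,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 split_fractions = split_fractions, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Random train/validation/test split of a windowed dataset
#'
#' Draws a uniformly random, seed-determined partition.  Partition sizes
#' are floor-based on the validation and test fractions, with the remainder
#' assigned to the training set; the same seed always yields the same
#' index sets.
#'
#' @param data A `windowed_dataset`.
#' @param config A [train_config()] (its `split_fractions` and `seed` are
#'   used), or a length-3 fraction vector.
#' @param seed Overrides the config seed when given.
#' @return List with `windowed_dataset`s `train`, `val`, `test`, plus
#'   `indices` (list of the three index vectors).
#' @export
split_dataset <- function(data, config = train_config(), seed = NULL) {
  stopifnot(inherits(data, "windowed_dataset"))
  if (is.numeric(config)) config <- train_config(split_fractions = config)
  fr <- config$split_fractions
  n <- dim(data$windows)[1]
  n_val <- floor(fr[2] * n)
  n_test <- floor(fr[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stopf("split (%d/%d/%d of %d) leaves an empty partition",
          n_train, n_val, n_test, n)
  perm <- with_seed(seed %||% config$seed, sample.int(n))
  idx <- list(train = sort(perm[seq_len(n_train)]),
              val = sort(perm[n_train + seq_len(n_val)]),
              test = sort(perm[n_train + n_val + seq_len(n_test)]))
  list(train = subset_windows(data, idx$train),
       val = subset_windows(data, idx$val),
       test = subset_windows(data, idx$test),
       indices = idx)
}

#' Session-based split for multi-session recordings
#'
#' Concatenates named sessions into training and test sets with no window
#' crossing the partition — the protocol used for the BCI IV-2a recipe
#' (1 train / 1 test session) and IV-2b (3 train / 2 test).
#'
#' @param sessions Named list of `windowed_dataset`s, one per session.
#' @param train_sessions,test_sessions Character vectors of session names;
#'   must be disjoint and present.
#' @return List with `windowed_dataset`s `train` and `test`.
#' @export
session_split <- function(sessions, train_sessions, test_sessions) {
  if (length(intersect(train_sessions, test_sessions)))
    stopf("sessions %s appear in both partitions",
          paste(intersect(train_sessions, test_sessions), collapse = ", "))
  missing <- setdiff(c(train_sessions, test_sessions), names(sessions))
  if (length(missing)) stopf("unknown session(s): %s", paste(missing, collapse = ", "))
  cat_sets <- function(nms) Reduce(combine_windows, sessions[nms])
  list(train = cat_sets(train_sessions), test = cat_sets(test_sessions))
}

resolve_loss <- function(loss, n_classes) {
  if (loss == "auto") { if (n_classes == 2) "binary" else "categorical" }
  else loss
}

onehot <- function(labels, K) {
  Y <- matrix(0, length(labels), K)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

# core optimization loop; expects RNG already seeded by the caller
train_loop <- function(net, x_train, y_train, x_val, y_val, config, verbose) {
  K <- net$spec$n_classes
  loss_type <- resolve_loss(config$loss, K)
  n <- dim(x_train)[1]
  opt <- adam_init(net$params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  best <- list(val_acc = -Inf, epoch = NA_integer_, params = net$params,
               bn = net$bn)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0; ep_correct <- 0
    for (bi in batches) {
      xb <- x_train[bi, , , drop = FALSE]
      yb <- onehot(y_train[bi], K)
      fwd <- net_forward(net, xb, train = TRUE)
      lg <- loss_grad(fwd$probs, yb, loss_type)
      if (!is.finite(lg$loss))
        stopf("loss became non-finite at epoch %d; lower the learning rate", epoch)
      grads <- net_backward(net, fwd, lg$dlogits)
      st <- adam_step(net$params, grads, opt, config$learning_rate)
      net$params <- apply_maxnorm(st$params, net$spec)
      opt <- st$state
      net$bn <- fwd$new_bn
      ep_loss <- ep_loss + lg$loss * length(bi)
      ep_correct <- ep_correct +
        sum(max.col(fwd$probs, ties.method = "first") == y_train[bi])
    }
    val <- evaluate_probs(net, x_val, y_val, loss_type)
    hist[epoch, ] <- list(epoch, ep_loss / n, ep_correct / n,
                          val$loss, val$acc)
    if (val$acc > best$val_acc) {
      best <- list(val_acc = val$acc, epoch = epoch, params = net$params,
                   bn = net$bn)
      if (!is.null(config$checkpoint_dir)) {
        dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(list(params = net$params, bn = net$bn, epoch = epoch),
                file.path(config$checkpoint_dir, "best_weights.rds"))
      }
    }
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
                      epoch, ep_loss / n, ep_correct / n, val$loss, val$acc))
  }
  # restore the best-validation checkpoint
  if (is.finite(best$val_acc)) {
    net$params <- best$params
    net$bn <- best$bn
  }
  list(net = net, history = hist, best_epoch = best$epoch,
       best_val_acc = best$val_acc,
       best_weights_path = if (!is.null(config$checkpoint_dir))
         file.path(config$checkpoint_dir, "best_weights.rds") else NA_character_)
}

evaluate_probs <- function(net, x, y, loss_type) {
  probs <- net_forward(net, x, train = FALSE, keep_cache = FALSE)$probs
  lg <- loss_grad(probs, onehot(y, ncol(probs)), loss_type)
  list(loss = lg$loss, acc = mean(max.col(probs, ties.method = "first") == y),
       probs = probs)
}

#' Fit the multi-branch fusion network
#'
#' The package's main fitting function.  Builds the network from `spec`
#' (the published five-branch configuration by default), splits the data
#' 70/10/20 (or uses a supplied validation set), optimizes with Adam, and
#' after training restores the weights of the epoch with the best
#' validation accuracy.  All randomness — split, initialization, shuffling,
#' dropout — derives from `control$seed`, so identical calls reproduce
#' identical fits.
#'
#' @param x A `windowed_dataset`, or a numeric array (n x channels x
#'   window).
#' @param y Labels (integer 1..K or factor); taken from `x` when it is a
#'   `windowed_dataset`.
#' @param spec A [fusion_model_spec()]; defaults to
#'   [default_v2_spec()] for the data's geometry.
#' @param control A [train_config()].
#' @param validation Either `NULL` (carve the validation and test sets out
#'   of `x` via [split_dataset()]) or a list `list(x =, y =)` with an
#'   explicit validation set (then all of `x` trains and no test set is
#'   held out).
#' @param verbose Print per-epoch metrics.
#' @return An object of class `"eegnet_fusion"`: the fitted model, the
#'   per-epoch `history` (train/validation loss and accuracy), the best
#'   epoch, the held-out `test` set (when split internally) and the class
#'   names.  Methods: `print`, `summary`, `predict`, `plot`, `coef`.
#' @examples
#' \dontrun{
#' rec <- simulate_recording(synth_config(n_trials = 20, erd_depth = 0.8))
#' ws <- preprocess_recording(rec, "eegmmidb")
#' fit <- eegnet_fusion(ws, control = train_config(max_epochs = 5,
#'                                                 learning_rate = 1e-3))
#' predict(fit, fit$test)
#' }
#' @export
eegnet_fusion <- function(x, y = NULL, spec = NULL, control = train_config(),
                          validation = NULL, verbose = FALSE) {
  stopifnot(inherits(control, "train_config"))
  class_names <- NULL
  if (inherits(x, "windowed_dataset")) {
    class_names <- x$class_names
    dataset <- x
  } else {
    if (is.null(y)) stopf("y is required when x is a plain array")
    if (is.factor(y)) { class_names <- levels(y); y <- as.integer(y) }
    dataset <- structure(list(windows = x, labels = as.integer(y),
                              class_names = class_names %||%
                                sprintf("class%d", seq_len(max(y))),
                              sampling_rate_hz = NA_real_,
                              provenance = data.frame(
                                epoch = seq_len(dim(x)[1]), window = 1L)),
                         class = "windowed_dataset")
    class_names <- dataset$class_names
  }
  K <- length(class_names)
  d <- dim(dataset$windows)
  if (is.null(spec)) spec <- default_v2_spec(d[2], d[3], n_classes = K)
  stopifnot(inherits(spec, "fusion_model_spec"))
  if (spec$n_classes != K)
    stopf("spec declares %d classes but data has %d", spec$n_classes, K)

  test_set <- NULL
  fit <- with_seed(control$seed, {
    if (is.null(validation)) {
      sp <- split_dataset(dataset, control, seed = NULL)
      test_set <- sp$test
      tr <- sp$train; va <- sp$val
      x_tr <- tr$windows; y_tr <- tr$labels
      x_va <- va$windows; y_va <- va$labels
    } else {
      x_tr <- dataset$windows; y_tr <- dataset$labels
      vx <- validation$x
      x_va <- if (inherits(vx, "windowed_dataset")) vx$windows else vx
      y_va <- if (inherits(vx, "windowed_dataset")) vx$labels
              else as.integer(validation$y)
      if (!length(y_va)) stopf("validation set is empty")
    }
    net <- init_net(spec)
    if (control$max_epochs == 0) {
      list(net = net, history = data.frame(
             epoch = integer(), train_loss = numeric(), train_acc = numeric(),
             val_loss = numeric(), val_acc = numeric()),
           best_epoch = NA_integer_, best_val_acc = NA_real_,
           best_weights_path = NA_character_, test_set = test_set)
    } else {
      out <- train_loop(net, x_tr, y_tr, x_va, y_va, control, verbose)
      out$test_set <- test_set
      out
    }
  })
  model <- structure(list(spec = spec, net = fit$net,
                          summary = build_summary(spec, fit$net)),
                     class = "fusion_model")
  structure(list(model = model, spec = spec, control = control,
                 history = fit$history, best_epoch = fit$best_epoch,
                 best_val_acc = fit$best_val_acc,
                 best_weights_path = fit$best_weights_path,
                 class_names = class_names, test = fit$test_set,
                 loss = resolve_loss(control$loss, K)),
            class = "eegnet_fusion")
}

build_summary <- function(spec, net) {
  dims <- branch_feature_dims(spec)
  structure(list(per_branch_feature_dims = dims, fused_dim = sum(dims),
                 trainable_parameter_count = count_params(net),
                 n_branches = length(spec$branches)),
            class = "model_summary")
}

#' @export
print.eegnet_fusion <- function(x, ...) {
  cat(sprintf("Multi-branch fusion EEG classifier (%d branches, %s parameters)\n",
              length(x$spec$branches),
              format(x$model$summary$trainable_parameter_count, big.mark = ",")))
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs; best validation accuracy %.3f at epoch %d\n",
                nrow(x$history), x$best_val_acc, x$best_epoch))
  else cat("  untrained (max_epochs = 0)\n")
  invisible(x)
}

#' @export
summary.eegnet_fusion <- function(object, ...) object$model$summary

#' @export
predict.eegnet_fusion <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "windowed_dataset")) newdata$windows else newdata
  probs <- net_forward(object$model$net, x, train = FALSE, keep_cache = FALSE)$probs
  colnames(probs) <- object$class_names
  if (type == "prob") return(probs)
  cls <- max.col(probs, ties.method = "first")
  factor(object$class_names[cls], levels = object$class_names)
}

#' @export
coef.eegnet_fusion <- function(object, ...) object$model$net$params

#' @export
plot.eegnet_fusion <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) { warning("no training history to plot"); return(invisible(x)) }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "Loss", ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  plot(h$epoch, h$train_acc, type = "l", xlab = "epoch", ylab = "accuracy",
       main = "Accuracy", ylim = c(0, 1), ...)
  graphics::lines(h$epoch, h$val_acc, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  invisible(x)
}
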