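# Shared fixtures and independent oracles used across test files.

# Exhaustive per-sample one-vs-rest counting loop: the brute-force oracle
# the vectorized implementation is checked against.
brute_force_counts <- function(y_true, y_pred, focus) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_pred[i] == focus && y_true[i] == focus) tp <- tp + 1L
    else if (y_pred[i] == focus) fp <- fp + 1L
    else if (y_true[i] == focus) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Rank-based (Mann-Whitney) AUC of a score separating two label groups.
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n2 <- sum(label == 2)
  auc <- (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  max(auc, 1 - auc)
}

# Small labelled windowed dataset built directly (no preprocessing), for
# training/evaluation plumbing tests.
tiny_windowed <- function(n = 48, C = 3, W = 16, K = 2, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep_len(seq_len(K), n)
    windows <- array(stats::rnorm(n * C * W), c(n, C, W))
    # plant a crude class-dependent mean shift so tiny fits can overfit
    for (i in seq_len(n)) windows[i, 1, ] <- windows[i, 1, ] + labels[i]
    structure(list(windows = windows, labels = labels,
                   class_names = sprintf("class%d", seq_len(K)),
                   sampling_rate_hz = 160,
                   provenance = data.frame(epoch = seq_len(n), window = 1L)),
              class = "windowed_dataset")
  })
}

# Minimal two-branch spec small enough for numerical gradient checking.
tiny_spec <- function(C = 3, W = 16, K = 2, dropout = 0) {
  fusion_model_spec(
    list(branch_spec(2, 5, 3, 3, depth_multiplier = 2, pool1_len = 2,
                     pool2_len = 2, dropout_p = dropout),
         branch_spec(3, 4, 2, 4, depth_multiplier = 2, pool1_len = 2,
                     pool2_len = 3, dropout_p = dropout)),
    n_channels = C, window_len = W, n_classes = K)
}
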