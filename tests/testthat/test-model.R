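# Architecture specifications, structural bookkeeping, and gradients.

test_that("the default five-branch configuration carries the published sizes", {
  spec <- default_v2_spec(64, 80)
  expect_length(spec$branches, 5)
  tf <- sapply(spec$branches, `[[`, "n_temporal_filters")
  tk <- sapply(spec$branches, `[[`, "temporal_kernel_len")
  sf <- sapply(spec$branches, `[[`, "n_separable_filters")
  sk <- sapply(spec$branches, `[[`, "separable_kernel_len")
  expect_equal(tf, c(8, 16, 32, 64, 128))
  expect_equal(tk, c(64, 80, 96, 112, 128))
  expect_equal(sf, c(16, 32, 64, 128, 256))
  expect_equal(sk, c(8, 16, 32, 64, 128))
  expect_true(all(sapply(spec$branches, `[[`, "dropout_p") == 0.5))
})

test_that("filter-size ablation specs expose the tested kernel lengths", {
  tk <- function(s) sapply(s$branches, `[[`, "temporal_kernel_len")
  expect_equal(tk(test_config_spec(1, 8, 1024)), c(64, 128, 256, 512, 1024))
  expect_equal(tk(test_config_spec(3, 8, 1024)), c(64, 304, 544, 784, 1024))
  expect_equal(tk(test_config_spec(5, 8, 256)), c(64, 96, 128, 192, 256))
  expect_identical(test_config_spec(4, 8, 80), default_v2_spec(8, 80))
  expect_error(test_config_spec(6, 8, 80), "unknown")
})

test_that("model summary bookkeeping is consistent", {
  m <- build_model(default_v2_spec(8, 80), seed = 1)
  s <- summary(m)
  expect_equal(s$n_branches, 5)
  expect_equal(s$fused_dim, sum(s$per_branch_feature_dims))
  # window 80: pool 4 then 8 -> 2 time steps; dims = 2 * F2 per branch
  expect_equal(s$per_branch_feature_dims, 2 * c(16, 32, 64, 128, 256))
})

test_that("one-branch parameter count matches the layer-formula oracle", {
  C <- 7; W <- 96; K <- 3
  F1 <- 4; k <- 10; D <- 2; F2 <- 6; ks <- 5; p1 <- 4; p2 <- 4
  spec <- fusion_model_spec(list(branch_spec(F1, k, F2, ks, D, p1, p2)),
                            C, W, K)
  m <- build_model(spec, seed = 2)
  # layer-by-layer: temporal conv (no bias) + BN, depthwise spatial + BN,
  # separable (depthwise + pointwise, no bias) + BN, dense head with bias
  T2 <- (W %/% p1) %/% p2
  oracle <- (k * F1) + 2 * F1 +
    (C * F1 * D) + 2 * (F1 * D) +
    (ks * F1 * D) + (F1 * D * F2) + 2 * F2 +
    (F2 * T2) * K + K
  expect_equal(summary(m)$trainable_parameter_count, oracle)
})

test_that("softmax outputs normalize, are finite, and shape as (n, classes)", {
  m <- build_model(default_v2_spec(6, 80, n_classes = 3), seed = 3)
  withr::with_seed(1, x <- array(rnorm(5 * 6 * 80), c(5, 6, 80)))
  p <- predict(m, x)
  expect_equal(dim(p), c(5, 3))
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_error(predict(m, array(0, c(2, 4, 80))), "expects")
})

test_that("branch permutation preserves parameter count; appending grows it", {
  b <- lapply(1:3, function(i) branch_spec(2 * i, 8 * i, 4 * i, 4, 2, 2, 2))
  count <- function(br) summary(build_model(
    fusion_model_spec(br, 4, 32, 2), seed = 1))$trainable_parameter_count
  dims <- function(br) summary(build_model(
    fusion_model_spec(br, 4, 32, 2), seed = 1))$per_branch_feature_dims
  expect_equal(count(b), count(rev(b)))
  expect_equal(dims(rev(b)), rev(dims(b)))
  expect_gt(count(c(b, b[1])), count(b))
})

test_that("too-aggressive pooling for the window length is rejected", {
  expect_error(fusion_model_spec(list(branch_spec(2, 4, 2, 2, 2, 8, 8)),
                                 4, 32, 2), "pooling")
})

test_that("backpropagation matches numerical gradients", {
  ef <- asNamespace("eegfusion")
  spec <- tiny_spec()
  withr::with_seed(3, {
    net <- ef$init_net(spec)
    X <- array(rnorm(4 * 3 * 16), c(4, 3, 16))
    y <- sample(1:2, 4, TRUE)
  })
  Y <- ef$onehot(y, 2)
  for (loss_type in c("categorical", "binary")) {
    fwd <- ef$net_forward(net, X, train = TRUE)
    lg <- ef$loss_grad(fwd$probs, Y, loss_type)
    grads <- ef$net_backward(net, fwd, lg$dlogits)
    loss_at <- function(n2) {
      f <- ef$net_forward(n2, X, train = TRUE)
      ef$loss_grad(f$probs, Y, loss_type)$loss
    }
    for (nm in names(net$params)) {
      p <- net$params[[nm]]
      idx <- withr::with_seed(7, sample(length(p), min(4, length(p))))
      for (j in idx) {
        h <- 1e-6
        n2 <- net
        n2$params[[nm]][j] <- p[j] + h; lp <- loss_at(n2)
        n2$params[[nm]][j] <- p[j] - h; lm <- loss_at(n2)
        num <- (lp - lm) / (2 * h)
        expect_lt(abs(num - grads[[nm]][j]), 1e-6 + 1e-4 * abs(num))
      }
    }
  }
})

test_that("specs serialize to JSON and back losslessly", {
  spec <- test_config_spec(2, 22, 1125, n_classes = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(spec, path)
  expect_identical(read_model_spec(path), spec)
})
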