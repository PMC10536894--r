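# Split protocol, optimization loop, checkpoint restoration.

test_that("random split sizes follow floor arithmetic with remainder to train", {
  ws <- tiny_windowed(n = 37080 %/% 10, C = 2, W = 4)  # same arithmetic, smaller
  sp <- split_dataset(ws, train_config(seed = 5))
  expect_equal(lengths(sp$indices),
               c(train = 2597, val = 370, test = 741))
  expect_equal(sum(lengths(sp$indices)), 3708)
  expect_length(intersect(sp$indices$train, sp$indices$test), 0)
  expect_length(intersect(sp$indices$train, sp$indices$val), 0)
})

test_that("identical seeds give identical splits; degenerate fractions fail", {
  ws <- tiny_windowed(n = 50)
  s1 <- split_dataset(ws, train_config(seed = 3))
  s2 <- split_dataset(ws, train_config(seed = 3))
  expect_identical(s1$indices, s2$indices)
  s3 <- split_dataset(ws, train_config(seed = 4))
  expect_false(identical(s1$indices, s3$indices))
  expect_error(split_dataset(ws, train_config(split_fractions = c(1, 0, 0))),
               "empty")
})

test_that("session splits concatenate disjoint sessions", {
  sessions <- list(A = tiny_windowed(10, seed = 1), B = tiny_windowed(12, seed = 2),
                   C = tiny_windowed(8, seed = 3))
  sp <- session_split(sessions, c("A", "B"), "C")
  expect_equal(dim(sp$train$windows)[1], 22)
  expect_equal(dim(sp$test$windows)[1], 8)
  expect_error(session_split(sessions, c("A", "B"), c("B", "C")), "both")
  expect_error(session_split(sessions, "A", "Z"), "unknown")
})

test_that("a tiny separable set is overfit to perfect training accuracy", {
  ws <- tiny_windowed(n = 32, C = 3, W = 16)
  val <- tiny_windowed(n = 16, C = 3, W = 16, seed = 2)
  spec <- tiny_spec(dropout = 0)
  fit <- eegnet_fusion(ws, spec = spec,
                       control = train_config(learning_rate = 5e-3,
                                              max_epochs = 30, batch_size = 4,
                                              seed = 3),
                       validation = list(x = val))
  expect_equal(nrow(fit$history), 30)
  # the fitted network separates its own training windows perfectly
  pred <- predict(fit, ws, type = "class")
  expect_equal(mean(as.integer(pred) == ws$labels), 1)
})

test_that("restored weights reproduce the best recorded validation accuracy", {
  ef <- asNamespace("eegfusion")
  ws <- tiny_windowed(n = 60, C = 3, W = 16)
  fit <- eegnet_fusion(ws, spec = tiny_spec(dropout = 0.25),
                       control = train_config(learning_rate = 3e-3,
                                              max_epochs = 12, seed = 9))
  expect_equal(fit$history$val_acc[fit$best_epoch], max(fit$history$val_acc))
  # first occurrence wins on ties
  expect_equal(fit$best_epoch, which.max(fit$history$val_acc))
  # re-evaluating the restored network matches the checkpointed accuracy
  sp <- split_dataset(ws, train_config(seed = 9))
  rv <- ef$evaluate_probs(fit$model$net, sp$val$windows, sp$val$labels, fit$loss)
  expect_equal(rv$acc, max(fit$history$val_acc), tolerance = 1e-6)
})

test_that("zero epochs leave an untrained model with empty history", {
  ws <- tiny_windowed(n = 40)
  fit <- eegnet_fusion(ws, spec = tiny_spec(),
                       control = train_config(max_epochs = 0, seed = 1))
  expect_equal(nrow(fit$history), 0)
  expect_true(is.na(fit$best_epoch))
  expect_s3_class(predict(fit, ws, type = "class"), "factor")  # still usable
})

test_that("fitting is deterministic under a fixed seed", {
  ws <- tiny_windowed(n = 40)
  ctl <- train_config(learning_rate = 1e-3, max_epochs = 3, seed = 11)
  f1 <- eegnet_fusion(ws, spec = tiny_spec(dropout = 0.3), control = ctl)
  f2 <- eegnet_fusion(ws, spec = tiny_spec(dropout = 0.3), control = ctl)
  expect_identical(f1$model$net$params, f2$model$net$params)
  expect_identical(f1$history, f2$history)
})

test_that("on-disk checkpointing writes the best weights", {
  dir <- withr::local_tempdir()
  ws <- tiny_windowed(n = 40)
  fit <- eegnet_fusion(ws, spec = tiny_spec(),
                       control = train_config(learning_rate = 1e-3,
                                              max_epochs = 2, seed = 1,
                                              checkpoint_dir = dir))
  expect_true(file.exists(fit$best_weights_path))
  ck <- readRDS(fit$best_weights_path)
  expect_identical(ck$params, fit$model$net$params)
  expect_equal(ck$epoch, fit$best_epoch)
})
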