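# One-vs-rest confusion counts and derived metrics.

test_that("hand-countable example gives the expected counts", {
  cnt <- one_vs_rest_counts(c("L", "L", "R", "R"), c("L", "R", "R", "R"), "L")
  expect_equal(cnt, c(TP = 1, FP = 0, TN = 2, FN = 1))
  cnt_r <- one_vs_rest_counts(c("L", "L", "R", "R"), c("L", "R", "R", "R"), "R")
  expect_equal(cnt_r, c(TP = 2, FP = 1, TN = 1, FN = 0))
  expect_error(one_vs_rest_counts(c("L"), c("X"), "L", classes = c("L", "R")),
               "unknown")
})

test_that("perfect predictions give zero FP/FN and unit metrics", {
  y <- rep(c("L", "R", "F", "T"), 10)
  rep_ <- eval_report(y, y, classes = c("L", "R", "F", "T"))
  expect_equal(rep_$accuracy, 1)
  expect_true(all(rep_$per_class$FP == 0) && all(rep_$per_class$FN == 0))
  expect_true(all(rep_$per_class$f1 == 1))
})

test_that("counts and P/R/F1 match the brute-force oracle on random labels", {
  classes <- c("L", "R", "F", "T")
  withr::with_seed(9, {
    yt <- sample(classes, 1000, TRUE)
    yp <- sample(classes, 1000, TRUE)
  })
  rep_ <- eval_report(yt, yp, classes = classes)
  for (cl in classes) {
    oracle <- brute_force_counts(yt, yp, cl)
    row <- rep_$per_class[rep_$per_class$class == cl, ]
    expect_equal(unlist(row[c("TP", "FP", "TN", "FN")]),
                 oracle[c("TP", "FP", "TN", "FN")],
                 ignore_attr = TRUE)
    expect_equal(row$precision, oracle["TP"] / (oracle["TP"] + oracle["FP"]),
                 ignore_attr = TRUE)
    expect_equal(row$recall, oracle["TP"] / (oracle["TP"] + oracle["FN"]),
                 ignore_attr = TRUE)
    expect_equal(row$f1, 2 * row$precision * row$recall /
                   (row$precision + row$recall))
    expect_equal(sum(oracle), 1000)
  }
})

test_that("two-class identities hold: swapped-focus counts mirror", {
  withr::with_seed(2, {
    yt <- sample(c("L", "R"), 200, TRUE)
    yp <- sample(c("L", "R"), 200, TRUE)
  })
  cl <- one_vs_rest_counts(yt, yp, "L")
  cr <- one_vs_rest_counts(yt, yp, "R")
  expect_equal(cl[["TP"]], cr[["TN"]])
  expect_equal(cl[["FP"]], cr[["FN"]])
  rep_ <- eval_report(yt, yp, classes = c("L", "R"))
  expect_equal(rep_$accuracy, (cl[["TP"]] + cl[["TN"]]) / 200)
  expect_equal(rep_$accuracy, (cr[["TP"]] + cr[["TN"]]) / 200)
})

test_that("micro-averaged one-vs-rest recall equals accuracy", {
  classes <- letters[1:5]
  withr::with_seed(5, {
    yt <- sample(classes, 500, TRUE)
    yp <- sample(classes, 500, TRUE)
  })
  rep_ <- eval_report(yt, yp, classes = classes)
  micro <- sum(rep_$per_class$TP) / sum(rep_$per_class$TP + rep_$per_class$FN)
  expect_equal(micro, rep_$accuracy)
})

test_that("metrics are invariant under consistent class relabeling", {
  classes <- c("L", "R", "F", "T")
  withr::with_seed(7, {
    yt <- sample(classes, 300, TRUE)
    yp <- sample(classes, 300, TRUE)
  })
  r1 <- eval_report(yt, yp, classes = classes)
  perm <- c(L = "c3", R = "c1", F = "c4", T = "c2")
  r2 <- eval_report(perm[yt], perm[yp], classes = unname(perm))
  expect_equal(r2$accuracy, r1$accuracy)
  m1 <- r1$per_class[match(names(perm), r1$per_class$class),
                     c("precision", "recall", "f1")]
  m2 <- r2$per_class[match(unname(perm), r2$per_class$class),
                     c("precision", "recall", "f1")]
  expect_equal(m2, m1, ignore_attr = TRUE)
})

test_that("degenerate sets follow the zero-division convention with warning", {
  # single-class truth, focus on the absent class: no positives predicted/true
  warns <- capture_warnings(rep_ <- eval_report(rep("L", 5), rep("L", 5),
                                                classes = c("L", "R")))
  expect_match(warns, "recall|precision", all = TRUE)
  expect_length(warns, 2)
  row <- rep_$per_class[rep_$per_class$class == "R", ]
  expect_equal(row$f1, 0)
  l <- rep_$per_class[rep_$per_class$class == "L", ]
  expect_equal(l$recall, 1)
})

test_that("evaluate_model reports pooled metrics and timing on a fitted model", {
  ws <- tiny_windowed(n = 60, C = 3, W = 16)
  fit <- eegnet_fusion(ws, spec = tiny_spec(),
                       control = train_config(learning_rate = 3e-3,
                                              max_epochs = 6, seed = 2))
  rep_ <- evaluate_model(fit)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$n, 12)  # floor(0.2 * 60)
  expect_true(rep_$accuracy >= 0 && rep_$accuracy <= 1)
  expect_true(is.finite(rep_$mean_inference_time_s))  # reported, not asserted
  expect_equal(sum(rep_$per_class$TP), sum(diag(rep_$confusion)))
})
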