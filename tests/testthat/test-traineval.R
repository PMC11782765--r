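test_that("stratified split reproduces the published 70/30 counts", {
  counts <- c(CNV = 37206, DME = 11349, DRUSEN = 8617, NORMAL = 51140)
  plan <- stratified_split(counts, 0.3, seed = 1)
  expect_equal(plan$per_class$test, c(11162, 3405, 2585, 15342))
  expect_equal(sum(plan$per_class$test), 32494)
  expect_equal(plan$per_class$train + plan$per_class$test,
               unname(counts[plan$per_class$class]))
  # small case and determinism
  p10 <- stratified_split(c(A = 10), 0.3, seed = 2)
  expect_equal(p10$per_class$test, 3)
  expect_equal(p10$per_class$train, 7)
  expect_identical(stratified_split(counts, 0.3, seed = 5)$membership,
                   stratified_split(counts, 0.3, seed = 5)$membership)
  expect_error(stratified_split(counts, 1.2), "between 0 and 1")
})

test_that("confusion-matrix metrics match the loop oracle and identities", {
  set.seed(42)
  for (i in 1:50) {
    cm <- matrix(sample(0:30, 16, TRUE), 4, 4)
    if (sum(cm) == 0) cm[1, 1] <- 1
    rownames(cm) <- colnames(cm) <- oct_classes()
    got <- suppressWarnings(compute_metrics(cm))
    want <- metrics_oracle(cm)
    for (col in colnames(want))
      expect_equal(got$per_class[[col]], unname(want[, col]),
                   tolerance = 1e-12)
    expect_equal(got$accuracy, sum(diag(cm)) / sum(cm))
    # exact per-class identities where defined
    pc <- got$per_class
    ok <- stats::complete.cases(pc[c("fpr", "specificity", "fdr",
                                     "precision", "fnr", "sensitivity")])
    expect_equal(pc$fpr[ok] + pc$specificity[ok], rep(1, sum(ok)))
    expect_equal(pc$fdr[ok] + pc$precision[ok], rep(1, sum(ok)))
    expect_equal(pc$fnr[ok] + pc$sensitivity[ok], rep(1, sum(ok)))
  }
})

test_that("metric edge cases: perfect diagonal, single error, zero columns", {
  d <- diag(c(10, 10, 10, 10)); rownames(d) <- colnames(d) <- oct_classes()
  m <- compute_metrics(d)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro$fpr, 0); expect_equal(m$macro$fnr, 0)
  expect_equal(m$macro$fdr, 0); expect_equal(m$macro$mcc, 1)
  d2 <- d; d2[1, 1] <- 9; d2[1, 2] <- 1
  expect_equal(compute_metrics(d2)$accuracy, 39 / 40)
  # a never-predicted class yields NA precision with a warning
  cm0 <- matrix(0, 4, 4); cm0[, 1] <- 5
  rownames(cm0) <- colnames(cm0) <- oct_classes()
  expect_warning(m0 <- compute_metrics(cm0), "undefined")
  expect_true(anyNA(m0$per_class$precision))
})

test_that("evaluate tallies argmax predictions against true labels", {
  cfg <- tiny_occt_config(seed = 3L)
  model <- build_occt(cfg)
  ds <- phantom_dataset(3, seed = 50, side = 8)
  cm <- evaluate(model, ds)
  expect_equal(sum(cm), 12)
  expect_equal(dim(cm), c(4L, 4L))
  expect_equal(unname(rowSums(cm)), rep(3, 4))   # row = true class
  expect_error(evaluate(model, list(x = ds$x, y = NULL)), "unlabeled")
})

test_that("training history, loss decrease and seeded reproducibility", {
  cfg <- tiny_occt_config(seed = 11L)
  ds <- phantom_dataset(8, seed = 70, side = 8)
  tc <- train_config(epochs = 2, batch_size = 16, learning_rate = 0.003,
                     seed = 2)
  fit <- train_classifier(build_occt(cfg), ds, tc)
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$loss)))
  fit2 <- train_classifier(build_occt(cfg), ds, tc)
  expect_identical(fit$history, fit2$history)
  expect_error(train_classifier(build_occt(cfg),
                                list(x = ds$x[, , , 0, drop = FALSE],
                                     y = factor(character())), tc),
               "empty")
  # optimization sanity: loss decreases on a separable toy set
  toy <- list(x = array(c(rep(0, 8 * 8 * 3), rep(1, 8 * 8 * 3)),
                        c(8, 8, 3, 2)),
              y = factor(c("CNV", "DME"), levels = oct_classes()))
  fit3 <- train_classifier(build_occt(tiny_occt_config(seed = 4L)), toy,
                           train_config(epochs = 25, batch_size = 2,
                                        learning_rate = 0.01, seed = 3))
  expect_lt(fit3$history$loss[25], fit3$history$loss[1])
  expect_equal(fit3$history$accuracy[25], 1)
})

test_that("k-fold assignment stratifies, partitions and reproduces", {
  y <- factor(rep(oct_classes(), each = 25), levels = oct_classes())
  x <- array(runif(8 * 8 * 3 * 100), c(8, 8, 3, 100))
  cfg <- tiny_occt_config(seed = 5L)
  tc <- train_config(epochs = 1, batch_size = 32, seed = 5)
  res <- kfold_cv(cfg, tc, list(x = x, y = y), k = 10, seed = 8)
  expect_length(res$accuracies, 10)
  expect_true(all(res$accuracies >= 0 & res$accuracies <= 1))
  expect_equal(sort(unique(res$folds)), 1:10)
  expect_equal(unname(table(res$folds)), rep(10L, 10), ignore_attr = TRUE)
  # per-fold class proportions within one image of global proportions
  for (f in 1:10)
    expect_true(all(abs(table(y[res$folds == f]) - 2.5) <= 0.5))
  res2_folds <- kfold_cv(cfg, train_config(epochs = 1, batch_size = 32,
                                           seed = 5),
                         list(x = x, y = y), k = 10, seed = 8)$folds
  expect_identical(res$folds, res2_folds)
  expect_error(kfold_cv(cfg, tc, list(x = x, y = y), k = 1), "k must be")
})

test_that("reduction schedule recursion and curve plumbing", {
  expect_equal(reduction_schedule(130649, 0.75, 2), c(130649L, 97987L))
  expect_equal(reduction_schedule(1000, 0.75, 3), c(1000L, 750L, 563L))
  expect_equal(reduction_schedule(500, 1.0, 4), rep(500L, 4))
  expect_true(all(diff(reduction_schedule(10000, 0.75, 13)) < 0))
  ds <- phantom_dataset(20, seed = 90, side = 8)
  cfg <- tiny_occt_config(seed = 6L)
  tc <- train_config(epochs = 1, batch_size = 16, seed = 6)
  res <- reduction_curve(cfg, tc, ds, factor = 0.75, steps = 3, seed = 4)
  expect_length(res$accuracies, 3)
  expect_equal(res$sizes, reduction_schedule(80, 0.75, 3))
  # truncation warning when a step cannot fill a batch
  expect_warning(
    res2 <- reduction_curve(cfg, tc, ds, factor = 0.25, steps = 4, seed = 4),
    "truncated")
  expect_lt(length(res2$sizes), 4)
})
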