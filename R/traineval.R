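#' Classifier training configuration
#'
#' Defaults mirror the tuned protocol: 100 epochs, batch size 128, Adam
#' with learning rate 0.001, categorical cross-entropy. Final weights are
#' kept (fixed-epoch protocol, no early stopping).
#'
#' @param epochs,batch_size,learning_rate,optimizer,loss,seed Training
#'   hyperparameters.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L,
                         learning_rate = 0.001, optimizer = "adam",
                         loss = "categorical_crossentropy", seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split plan
#'
#' Per class, the test count is \code{round(test_frac * count)}
#' (round-half-up) and the remainder goes to training; test membership is
#' sampled uniformly without replacement under the seed.
#'
#' @param class_counts Named vector of per-class image counts (>= 1 each).
#' @param test_frac Test fraction, strictly inside (0, 1).
#' @param seed Integer sampling seed.
#' @return A \code{split_plan}: \code{per_class} data.frame (class, total,
#'   train, test), \code{membership} (per-class integer vectors of test
#'   indices) and the call parameters.
#' @export
stratified_split <- function(class_counts, test_frac = 0.3, seed = 1L) {
  if (test_frac <= 0 || test_frac >= 1)
    stop("test_frac must be strictly between 0 and 1")
  if (any(class_counts < 1)) stop("every class needs at least one image")
  classes <- names(class_counts) %||% paste0("class", seq_along(class_counts))
  test_n <- round_half_up(test_frac * as.numeric(class_counts))
  membership <- list()
  with_seed(seed, {
    for (i in seq_along(classes))
      membership[[classes[i]]] <- sort(sample.int(class_counts[[i]], test_n[i]))
  })
  per_class <- data.frame(class = classes,
                          total = as.numeric(class_counts),
                          train = as.numeric(class_counts) - test_n,
                          test = test_n, row.names = NULL,
                          stringsAsFactors = FALSE)
  structure(list(per_class = per_class, membership = membership,
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "split_plan")
}

one_hot <- function(y, levels_ = levels(y)) {
  m <- matrix(0, length(y), length(levels_))
  m[cbind(seq_along(y), as.integer(factor(y, levels = levels_)))] <- 1
  m
}

#' Predict class probabilities in batches
#'
#' @param model An \code{occt_model}.
#' @param x Image array \code{(side, side, 3, N)} in \[0, 1\].
#' @param batch_size Forward batch size.
#' @return \code{N x n_classes} matrix of probabilities.
#' @export
predict_proba <- function(model, x, batch_size = 256L) {
  N <- dim(x)[4]
  out <- matrix(0, N, model$cfg$n_classes)
  i <- 0L
  while (i < N) {
    m <- min(batch_size, N - i)
    out[(i + 1):(i + m), ] <-
      row_softmax(model$forward(x[, , , (i + 1):(i + m), drop = FALSE],
                                training = FALSE))
    i <- i + m
  }
  out
}

#' Train the classifier
#'
#' Mini-batch training of an OCCT model. Labels are one-hot encoded; the
#' loss acts on softmax probabilities and is chained through the softmax.
#' The final-epoch weights are the result (fixed-epoch protocol).
#'
#' @param model An \code{occt_model} from [build_occt()].
#' @param train_set \code{list(x = array(side, side, 3, N), y = factor)}.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return \code{list(model, history)} with per-epoch loss and accuracy.
#' @export
train_classifier <- function(model, train_set, cfg = train_config(),
                             verbose = FALSE) {
  x <- train_set$x; y <- train_set$y
  N <- dim(x)[4]
  if (N < 1) stop("empty training set")
  stopifnot(length(y) == N)
  Y <- one_hot(y)
  loss <- make_loss(cfg$loss)
  opt <- make_optimizer(cfg$optimizer, cfg$learning_rate)
  nb <- min(cfg$batch_size, N)
  hist <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                     accuracy = NA_real_)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      tot_loss <- 0; tot_correct <- 0
      for (start in seq(1, N, by = nb)) {
        idx <- ord[start:min(start + nb - 1, N)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        logits <- model$forward(xb, training = TRUE)
        p <- row_softmax(logits)
        tot_loss <- tot_loss + loss$value(p, yb) * length(idx)
        tot_correct <- tot_correct +
          sum(max.col(p, ties.method = "first") == max.col(yb))
        dz <- if (cfg$loss == "categorical_crossentropy")
          (p - yb) / nrow(p) else softmax_vjp(p, loss$grad(p, yb))
        zero_grads(model$params)
        model$backward(dz)
        opt$step(model$params)
      }
      hist$loss[ep] <- tot_loss / N
      hist$accuracy[ep] <- tot_correct / N
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.4f acc %.3f", ep, cfg$epochs,
                        hist$loss[ep], hist$accuracy[ep]))
    }
  })
  list(model = model, history = hist)
}

#' Evaluate into a confusion matrix
#'
#' Argmax predictions tallied into a true-by-predicted contingency table.
#'
#' @param model An \code{occt_model}.
#' @param test_set \code{list(x, y)} as in [train_classifier()].
#' @return A \code{K x K} integer matrix; rows are true labels, columns
#'   predictions.
#' @export
evaluate <- function(model, test_set) {
  y <- test_set$y
  if (is.null(y) || anyNA(y)) stop("evaluate: unlabeled images in test set")
  p <- predict_proba(model, test_set$x)
  pred <- factor(levels(y)[max.col(p, ties.method = "first")],
                 levels = levels(y))
  cm <- table(true = y, predicted = pred)
  matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
}

#' Eleven-metric confusion-matrix report
#'
#' One-vs-rest TP/TN/FP/FN per class with the standard formulas
#' (precision, recall, F1, specificity, sensitivity, NPV, FPR, FNR, FDR,
#' MCC), macro (unweighted) and support-weighted averages, and overall
#' accuracy (trace / total). All rates are fractions in \[0, 1\]. A class
#' metric with a zero denominator is reported as \code{NA} and excluded
#' from the averages with a warning.
#'
#' @param cm Square true-by-predicted count matrix.
#' @return A \code{metrics_report} list: \code{per_class} data.frame,
#'   \code{macro}, \code{weighted}, \code{accuracy}, \code{total}.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  K <- nrow(cm)
  classes <- rownames(cm) %||% paste0("class", seq_len(K))
  sdiv <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  rows <- lapply(seq_len(K), function(i) {
    TP <- cm[i, i]
    FN <- sum(cm[i, ]) - TP
    FP <- sum(cm[, i]) - TP
    TN <- total - TP - FN - FP
    precision <- sdiv(TP, TP + FP)
    recall <- sdiv(TP, TP + FN)
    specificity <- sdiv(TN, TN + FP)
    npv <- sdiv(TN, TN + FN)
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
    mcc <- if (mcc_den > 0) (TP * TN - FP * FN) / mcc_den else NA_real_
    data.frame(class = classes[i], support = TP + FN, precision = precision,
               recall = recall, f1 = f1, specificity = specificity,
               sensitivity = recall, npv = npv,
               fpr = sdiv(FP, FP + TN), fnr = sdiv(FN, FN + TP),
               fdr = sdiv(FP, FP + TP), mcc = mcc,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_class), c("class", "support"))
  if (anyNA(per_class[metric_cols]))
    warning("some per-class metrics are undefined (zero denominator); ",
            "they are excluded from the averages")
  macro <- lapply(per_class[metric_cols], function(v) mean(v, na.rm = TRUE))
  wts <- per_class$support / sum(per_class$support)
  weighted <- lapply(per_class[metric_cols], function(v) {
    ok <- !is.na(v)
    sum(v[ok] * wts[ok]) / sum(wts[ok])
  })
  structure(list(per_class = per_class, macro = macro, weighted = weighted,
                 accuracy = sum(diag(cm)) / total, total = total),
            class = "metrics_report")
}

#' Stratified k-fold cross-validation
#'
#' Per class, shuffled indices are dealt round-robin into k folds (fold
#' class proportions within one image of the global ones); each fold is
#' held out once against a freshly built and trained model.
#'
#' @param model_cfg An [occt_config()].
#' @param train_cfg A [train_config()].
#' @param dataset \code{list(x, y)}.
#' @param k Number of folds (>= 2).
#' @param seed Fold-assignment seed.
#' @return \code{list(accuracies, folds)}; \code{folds} is the per-image
#'   fold id.
#' @export
kfold_cv <- function(model_cfg, train_cfg, dataset, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  y <- dataset$y
  N <- length(y)
  if (N < k) stop("dataset smaller than k")
  folds <- integer(N)
  with_seed(seed, {
    off <- 0L   # rotate the round-robin start so fold sizes stay balanced
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- ((seq_along(idx) - 1L + off) %% k) + 1L
      off <- off + length(idx)
    }
  })
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    cfg_f <- model_cfg; cfg_f$seed <- model_cfg$seed + f
    model <- build_occt(cfg_f)
    fit <- train_classifier(model,
                            list(x = dataset$x[, , , tr, drop = FALSE],
                                 y = droplevels(y[tr])),
                            train_cfg)
    cm <- evaluate(fit$model,
                   list(x = dataset$x[, , , !tr, drop = FALSE],
                        y = y[!tr]))
    acc[f] <- sum(diag(cm)) / sum(cm)
  }
  list(accuracies = acc, folds = folds)
}

#' Dataset-reduction schedule
#'
#' `size[i + 1] = round(factor * size[i])` (round-half-up), starting at
#' the full dataset.
#'
#' @param start Full dataset size.
#' @param factor Retention factor per step (0.75 keeps 75\%).
#' @param steps Number of evaluations.
#' @return Integer vector of sizes, length \code{steps}.
#' @export
reduction_schedule <- function(start, factor = 0.75, steps = 13L) {
  stopifnot(start >= 1, factor > 0, factor <= 1, steps >= 1)
  sizes <- numeric(steps)
  sizes[1] <- start
  for (i in seq_len(steps - 1)) sizes[i + 1] <- round_half_up(factor * sizes[i])
  as.integer(sizes)
}

#' Dataset-reduction robustness curve
#'
#' At each schedule step a stratified, nested subsample (step i+1 is a
#' subset of step i) is split 70/30, a fresh model is trained on the
#' training part and test accuracy recorded. The schedule is truncated
#' with a warning once a step cannot fill one training batch.
#'
#' @param model_cfg An [occt_config()].
#' @param train_cfg A [train_config()].
#' @param dataset \code{list(x, y)}.
#' @param factor,steps See [reduction_schedule()].
#' @param test_frac Held-out fraction within each step.
#' @param seed Subsampling seed.
#' @return \code{list(sizes, accuracies)}.
#' @export
reduction_curve <- function(model_cfg, train_cfg, dataset, factor = 0.75,
                            steps = 13L, test_frac = 0.3, seed = 1L) {
  y <- dataset$y
  N <- length(y)
  sizes <- reduction_schedule(N, factor, steps)
  keep <- sizes >= ceiling(train_cfg$batch_size / (1 - test_frac))
  if (!all(keep)) {
    warning("reduction schedule truncated at step ", which(!keep)[1] - 1,
            ": remaining sizes cannot fill one training batch")
    sizes <- sizes[keep]
  }
  # one shuffled per-class order; every step takes prefixes (nested)
  ord <- list()
  with_seed(seed, {
    for (cl in levels(y)) ord[[cl]] <- sample(which(y == cl))
  })
  props <- table(y) / N
  acc <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    per_cl <- round_half_up(sizes[i] * as.numeric(props))
    per_cl <- pmin(per_cl, vapply(ord, length, 0L))
    idx <- unlist(lapply(seq_along(ord), function(j)
      ord[[j]][seq_len(per_cl[j])]), use.names = FALSE)
    yy <- y[idx]
    plan <- stratified_split(table(yy), test_frac, seed = seed + i)
    test_mask <- logical(length(idx))
    off <- 0L
    for (cl in names(plan$membership)) {
      cl_pos <- which(yy == cl)
      test_mask[cl_pos[plan$membership[[cl]]]] <- TRUE
    }
    cfg_i <- model_cfg; cfg_i$seed <- model_cfg$seed + i
    model <- build_occt(cfg_i)
    fit <- train_classifier(model,
                            list(x = dataset$x[, , , idx[!test_mask], drop = FALSE],
                                 y = yy[!test_mask]),
                            train_cfg)
    cm <- evaluate(fit$model,
                   list(x = dataset$x[, , , idx[test_mask], drop = FALSE],
                        y = yy[test_mask]))
    acc[i] <- sum(diag(cm)) / sum(cm)
  }
  list(sizes = sizes, accuracies = acc)
}
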