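# Independent brute-force oracles. These deliberately use naive loops and
# direct formulas, never the package's own kernels.

erode_oracle <- function(img, k) {
  r <- k %/% 2
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (y in seq_len(H)) for (x in seq_len(W)) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r) {
      yy <- min(max(y + dy, 1), H)
      xx <- min(max(x + dx, 1), W)
      vals <- c(vals, img[yy, xx])
    }
    out[y, x] <- min(vals)
  }
  out
}

median_oracle <- function(img, k) {
  r <- k %/% 2
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (y in seq_len(H)) for (x in seq_len(W)) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r) {
      yy <- min(max(y + dy, 1), H)
      xx <- min(max(x + dx, 1), W)
      vals <- c(vals, img[yy, xx])
    }
    out[y, x] <- sort(vals)[(length(vals) + 1) %/% 2]
  }
  out
}

seqpool_oracle <- function(tokens, w, b) {
  g <- nrow(tokens); e <- ncol(tokens)
  logits <- numeric(g)
  for (j in seq_len(g)) {
    s <- b
    for (d in seq_len(e)) s <- s + tokens[j, d] * w[d]
    logits[j] <- s
  }
  ex <- exp(logits - max(logits))
  wt <- ex / sum(ex)
  pooled <- numeric(e)
  for (d in seq_len(e))
    for (j in seq_len(g)) pooled[d] <- pooled[d] + wt[j] * tokens[j, d]
  list(pooled = pooled, weights = wt)
}

# Direct-formula SSIM: explicit loops over 11x11 Gaussian windows.
ssim_oracle <- function(a, b) {
  r <- 5L
  gw <- exp(-((-r:r)^2) / (2 * 1.5^2)); gw <- gw / sum(gw)
  W2 <- outer(gw, gw)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (y in (r + 1):(H - r)) for (x in (r + 1):(W - r)) {
    pa <- a[(y - r):(y + r), (x - r):(x + r)]
    pb <- b[(y - r):(y + r), (x - r):(x + r)]
    mu1 <- sum(W2 * pa); mu2 <- sum(W2 * pb)
    s11 <- sum(W2 * pa * pa) - mu1^2
    s22 <- sum(W2 * pb * pb) - mu2^2
    s12 <- sum(W2 * pa * pb) - mu1 * mu2
    vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
                ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
  }
  mean(vals)
}

# Loop-based one-vs-rest confusion-matrix metrics.
metrics_oracle <- function(cm) {
  K <- nrow(cm); total <- sum(cm)
  out <- list()
  for (i in seq_len(K)) {
    TP <- cm[i, i]
    FN <- 0; for (j in seq_len(K)) if (j != i) FN <- FN + cm[i, j]
    FP <- 0; for (j in seq_len(K)) if (j != i) FP <- FP + cm[j, i]
    TN <- total - TP - FN - FP
    dv <- function(n, d) if (d > 0) n / d else NA_real_
    pre <- dv(TP, TP + FP); rec <- dv(TP, TP + FN)
    mden <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
    out[[i]] <- c(
      precision = pre, recall = rec,
      f1 = if (!is.na(pre) && !is.na(rec) && pre + rec > 0)
        2 * pre * rec / (pre + rec) else NA_real_,
      specificity = dv(TN, TN + FP), sensitivity = rec,
      npv = dv(TN, TN + FN), fpr = dv(FP, FP + TN), fnr = dv(FN, FN + TP),
      fdr = dv(FP, FP + TP),
      mcc = if (mden > 0) (TP * TN - FP * FN) / mden else NA_real_)
  }
  do.call(rbind, out)
}

numerical_gradient <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

tiny_occt_config <- function(...) {
  occt_config(embed_dim = 8L, tokenizer_channels = c(4L, 8L), n_heads = 2L,
              mlp_hidden = 16L, dropout = 0, input_size = 8L, ...)
}
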