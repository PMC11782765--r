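test_that("tokenizer geometry follows the two stride-2 pools", {
  cfg <- occt_config()
  tok <- build_tokenizer(cfg)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  tk <- tok$forward(x)
  expect_equal(attr(tk, "g"), 64)          # 32 -> 16 -> 8
  expect_equal(dim(tk), c(64 * 2, 128))
  cfg224 <- occt_config(input_size = 224L)
  tok224 <- build_tokenizer(cfg224)
  x224 <- array(runif(224 * 224 * 3), c(224, 224, 3, 1))
  expect_equal(attr(tok224$forward(x224), "g"), 56 * 56)
  # stage-1 width is 64 regardless of kernel
  for (k in c(1, 5)) {
    t2 <- build_tokenizer(occt_config(tokenizer_kernel = k))
    expect_equal(nrow(t2$layers[[1]]$W$value), 64)
  }
  expect_error(build_tokenizer(occt_config(tokenizer_kernel = 5,
                                           input_size = 4L)), "kernel")
})

test_that("encoder block preserves shape, is identity at zero maps, and is
           permutation-equivariant", {
  cfg <- tiny_occt_config()
  blk <- build_encoder_block(cfg)
  g <- 6; N <- 3
  x <- matrix(rnorm(g * N * cfg$embed_dim), g * N)
  y <- blk$forward(x, FALSE, g = g)
  expect_equal(dim(y), dim(x))
  # zero attention-out and MLP-out projections -> residuals pass x through
  blk$msa$Wo$value[] <- 0; blk$msa$bo$value[] <- 0
  blk$fc2$W$value[] <- 0; blk$fc2$b$value[] <- 0
  expect_equal(blk$forward(x, FALSE, g = g), x)
  # permutation equivariance (no positional embedding)
  blk2 <- build_encoder_block(cfg)
  perm <- c(4, 1, 6, 2, 5, 3)
  xp <- x
  for (n in 1:N) xp[(n - 1) * g + seq_len(g), ] <-
    x[(n - 1) * g + perm, ]
  y1 <- blk2$forward(x, FALSE, g = g)
  y2 <- blk2$forward(xp, FALSE, g = g)
  y1p <- y1
  for (n in 1:N) y1p[(n - 1) * g + seq_len(g), ] <- y1[(n - 1) * g + perm, ]
  expect_equal(y2, y1p, tolerance = 1e-12)
  expect_error(occt_config(embed_dim = 9L, tokenizer_channels = c(4L, 9L),
                           n_heads = 2L), "n_heads")
})

test_that("sequence pooling limits and brute-force oracle", {
  e <- 5
  # single token: softmax of one logit is 1 -> identity
  one <- matrix(rnorm(e), 1)
  expect_equal(sequence_pool(one, rnorm(e), 0.3)$pooled, as.vector(one))
  # zero scoring map -> arithmetic token mean
  tk <- matrix(rnorm(7 * e), 7)
  expect_equal(sequence_pool(tk, rep(0, e), 0)$pooled, colMeans(tk))
  expect_error(sequence_pool(tk[0, , drop = FALSE], rep(0, e)), "empty")
  set.seed(13)
  for (i in 1:50) {
    g <- sample(1:12, 1)
    tk <- matrix(rnorm(g * e), g)
    w <- rnorm(e); b <- rnorm(1)
    got <- sequence_pool(tk, w, b)
    want <- seqpool_oracle(tk, w, b)
    expect_equal(got$pooled, want$pooled, tolerance = 1e-9)
    expect_equal(got$weights, want$weights, tolerance = 1e-9)
    expect_equal(sum(got$weights), 1, tolerance = 1e-9)
  }
})

test_that("full model emits a softmax simplex and is build-deterministic", {
  cfg <- tiny_occt_config(seed = 5L)
  m <- build_occt(cfg)
  x <- array(runif(8 * 8 * 3 * 7), c(8, 8, 3, 7))
  p <- m$predict(x)
  expect_equal(dim(p), c(7L, 4L))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  # extremes stay finite
  expect_true(all(is.finite(m$forward(array(0, c(8, 8, 3, 2))))))
  expect_true(all(is.finite(m$forward(array(255, c(8, 8, 3, 2))))))
  # identical seeds give identical initial weights
  m2 <- build_occt(cfg)
  expect_identical(lapply(m$params, function(p) p$value),
                   lapply(m2$params, function(p) p$value))
})

test_that("parameter counting reproduces the reconstructed budgets", {
  m <- build_occt(occt_config())
  expect_identical(count_parameters(m), 241925L)
  # closed-form enumeration of every trainable tensor
  tok <- 3 * 64 * 9 + 64 + 64 * 128 * 9 + 128
  blk <- 2 * 256 + (128 * 384 + 384) + (128 * 128 + 128) +
    (128 * 384 + 384) + (384 * 128 + 128)
  expect_identical(count_parameters(m),
                   as.integer(tok + blk + 256 + 129 + (128 * 4 + 4)))
  expect_equal(tok, 75648)
  expect_equal(blk, 165376)
  # each extra block adds exactly one block of parameters
  expect_identical(count_parameters(build_occt(occt_config(n_blocks = 2))) -
                     count_parameters(m), 165376L)
  # independent of stride and input size (no positional embedding)
  expect_identical(count_parameters(build_occt(occt_config(conv_stride = 2L))),
                   241925L)
  expect_identical(count_parameters(build_occt(occt_config(input_size = 64L))),
                   241925L)
})

test_that("ablation grid has 32 sequentially-conditioned configurations", {
  grid <- ablation_grid()
  expect_length(grid, 3 + 5 + 8 + 2 + 5 + 4 + 5)
  s7 <- Filter(function(g) g$study == 7, grid)
  expect_true(all(vapply(s7, function(g) g$config$learning_rate, 0) == 0.001))
  expect_true(all(vapply(s7, function(g) g$config$activation, "") == "elu"))
  expect_true(all(vapply(s7, function(g) g$config$optimizer, "") == "adam"))
  # study 1 varies blocks at kernel 3
  s1 <- Filter(function(g) g$study == 1, grid)
  expect_equal(vapply(s1, function(g) g$config$n_blocks, 0L), 1:3)
  expect_true(all(vapply(s1, function(g) g$config$tokenizer_kernel, 0L) == 3L))
  # the winners chain terminates at the default configuration
  winners <- occt_config()
  last <- s7[[1]]$config
  for (f in c("n_blocks", "tokenizer_kernel", "activation", "pool",
              "optimizer", "learning_rate", "loss"))
    expect_identical(last[[f]], winners[[f]])
})
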