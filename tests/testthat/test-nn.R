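# Numerical gradient checks for every layer family the models use. These
# guard the hand-written backward passes; shapes are tiny on purpose.

test_that("conv, transposed conv and pooling backward passes are exact", {
  set.seed(21)
  l <- layer_conv2d(2, 3, 3, stride = 2)
  x <- array(rnorm(2 * 7 * 6 * 2), c(2, 7, 6, 2))
  y <- l$forward(x)
  d <- array(rnorm(length(y)), dim(y))
  zero_grads(l$params)
  dx <- l$backward(d)
  expect_lt(max(abs(dx - numerical_gradient(
    function(z) sum(l$forward(z) * d), x))), 1e-7)
  fw <- function(w) { old <- l$W$value; l$W$value <- w
    r <- sum(l$forward(x) * d); l$W$value <- old; r }
  expect_lt(max(abs(l$W$grad - numerical_gradient(fw, l$W$value))), 1e-7)

  lt <- layer_tconv2d(3, 2, 4, 2)
  xt <- array(rnorm(3 * 4 * 5 * 2), c(3, 4, 5, 2))
  yt <- lt$forward(xt)
  expect_equal(dim(yt), c(2L, 8L, 10L, 2L))   # spatial size doubles
  dt <- array(rnorm(length(yt)), dim(yt))
  zero_grads(lt$params)
  dxt <- lt$backward(dt)
  expect_lt(max(abs(dxt - numerical_gradient(
    function(z) sum(lt$forward(z) * dt), xt))), 1e-7)
  fwt <- function(w) { old <- lt$W$value; lt$W$value <- w
    r <- sum(lt$forward(xt) * dt); lt$W$value <- old; r }
  expect_lt(max(abs(lt$W$grad - numerical_gradient(fwt, lt$W$value))), 1e-7)

  for (tp in c("max", "average")) {
    lp <- layer_pool(tp, 3, 2)
    xp <- array(rnorm(2 * 9 * 8 * 2), c(2, 9, 8, 2))
    yp <- lp$forward(xp)
    dp <- array(rnorm(length(yp)), dim(yp))
    expect_lt(max(abs(lp$backward(dp) - numerical_gradient(
      function(z) sum(lp$forward(z) * dp), xp))), 1e-7)
  }
})

test_that("normalization and attention backward passes are exact", {
  set.seed(22)
  lb <- layer_batchnorm(3)
  xb <- array(rnorm(3 * 5 * 4 * 3), c(3, 5, 4, 3))
  yb <- lb$forward(xb, training = TRUE)
  db <- array(rnorm(length(yb)), dim(yb))
  zero_grads(lb$params)
  expect_lt(max(abs(lb$backward(db) - numerical_gradient(
    function(z) sum(lb$forward(z, TRUE) * db), xb))), 1e-6)

  ll <- layer_layernorm(6)
  xl <- matrix(rnorm(30), 5)
  yl <- ll$forward(xl)
  dl <- matrix(rnorm(30), 5)
  zero_grads(ll$params)
  expect_lt(max(abs(ll$backward(dl) - numerical_gradient(
    function(z) sum(ll$forward(z) * dl), xl))), 1e-6)

  lm <- layer_msa(8, 2, dropout = 0)
  xm <- matrix(rnorm(2 * 4 * 8), 8)
  ym <- lm$forward(xm, FALSE, g = 4)
  dm <- matrix(rnorm(length(ym)), nrow(ym))
  zero_grads(lm$params)
  expect_lt(max(abs(lm$backward(dm) - numerical_gradient(
    function(z) sum(lm$forward(z, FALSE, g = 4) * dm), xm))), 1e-7)
  fq <- function(w) { old <- lm$Wqkv$value; lm$Wqkv$value <- w
    r <- sum(lm$forward(xm, FALSE, g = 4) * dm); lm$Wqkv$value <- old; r }
  expect_lt(max(abs(lm$Wqkv$grad - numerical_gradient(fq, lm$Wqkv$value))),
            1e-7)
})

test_that("the assembled classifier is exact end to end", {
  set.seed(23)
  m <- build_occt(tiny_occt_config(n_blocks = 2L, seed = 2L))
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  lg <- m$forward(x)
  d <- matrix(rnorm(length(lg)), nrow(lg))
  zero_grads(m$params)
  dx <- m$backward(d)
  expect_lt(max(abs(dx - numerical_gradient(
    function(z) sum(m$forward(z) * d), x))), 1e-7)
  for (p in m$params[c(1, 5, 9, length(m$params))]) {
    fp <- function(v) { old <- p$value; p$value <- v
      r <- sum(m$forward(x) * d); p$value <- old; r }
    expect_lt(max(abs(p$grad - numerical_gradient(fp, p$value))), 1e-6)
  }
})

test_that("activations match their derivatives", {
  set.seed(24)
  x <- matrix(rnorm(40, 0, 2), 8)
  for (nm in c("relu", "elu", "tanh", "softplus", "softsign", "leaky_relu",
               "gelu", "sigmoid")) {
    l <- layer_activation(nm)
    y <- l$forward(x)
    d <- matrix(rnorm(40), 8)
    got <- l$backward(d)
    num <- numerical_gradient(function(z) sum(l$forward(z) * d), x)
    expect_lt(max(abs(got - num)), 1e-6)
  }
})

test_that("losses agree with direct formulas and softmax chaining", {
  set.seed(25)
  p <- row_softmax(matrix(rnorm(9), 3))
  y <- one_hot(factor(c("a", "b", "c")))
  for (nm in c("categorical_crossentropy", "binary_crossentropy",
               "mean_squared_error", "mean_squared_logarithmic_error",
               "mean_absolute_error")) {
    ls <- make_loss(nm)
    expect_true(is.finite(ls$value(p, y)))
    g <- ls$grad(p, y)
    num <- numerical_gradient(function(q) ls$value(q, y), p, eps = 1e-6)
    expect_lt(max(abs(g - num)), 1e-4)
  }
  # cce gradient through softmax equals the (p - y)/n shortcut
  z <- matrix(rnorm(9), 3)
  pz <- row_softmax(z)
  cce <- make_loss("categorical_crossentropy")
  expect_equal(softmax_vjp(pz, cce$grad(pz, y)), (pz - y) / nrow(pz),
               tolerance = 1e-9)
})
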