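# GAN unit tests run at image_size 16 (the smallest the four doubling
# stages allow) to stay fast; geometry at the default 224 is covered in the
# acceptance suite.

test_that("generator maps noise to images of the configured geometry", {
  cfg <- gan_config(image_size = 16L, seed = 2L)
  gen <- build_generator(cfg)
  z1 <- matrix(rnorm(100), 1)
  y1 <- gen$forward(z1)
  expect_equal(dim(y1), c(16L, 16L, 3L, 1L))
  expect_true(all(abs(y1) <= 1))          # tanh head
  z5 <- matrix(rnorm(5 * 100), 5)
  expect_equal(dim(gen$forward(z5))[4], 5L)
  # same weights + same noise -> identical output (inference determinism)
  expect_identical(gen$forward(z1), gen$forward(z1))
  # batch-size invariance of per-image output
  expect_equal(gen$forward(z5)[, , , 1], gen$forward(z5[1:2, ])[, , , 1],
               tolerance = 1e-12)
  # inconsistent stage sizes are a construction error
  bad <- generator_spec(cfg); bad$sizes <- c(2L, 4L, 8L, 32L)
  expect_error(build_generator(cfg, bad), "double|image_size")
})

test_that("discriminator bounds, geometry checks and determinism", {
  cfg <- gan_config(image_size = 16L, seed = 3L)
  disc <- build_discriminator(cfg)
  x <- array(runif(16 * 16 * 3 * 4, -1, 1), c(16, 16, 3, 4))
  p <- discriminate(disc, x)
  expect_length(p, 4)
  expect_true(all(p > 0 & p < 1))
  expect_error(disc$forward(array(0, c(8, 8, 3, 1))), "expects")
  expect_identical(discriminate(disc, x), discriminate(disc, x))
})

test_that("training alternates updates and freezes the idle network", {
  set.seed(4)
  n <- 16
  x <- array(runif(16 * 16 * 3 * n) * 255, c(16, 16, 3, n))
  cfg <- gan_config(image_size = 16L, batch_size = 8L, seed = 4L)
  expect_error(train_dcgan(x[, , , 1:4, drop = FALSE], cfg),
               "at least one batch")
  fit <- train_dcgan(x, cfg, steps = 5)
  expect_equal(nrow(fit$history), 5)
  expect_true(all(is.finite(unlist(fit$history[c("d_loss", "g_loss", "value")]))))
  # accounting identity on synthesized output range
  imgs <- synthesize(fit$generator, 3, seed = 7)
  expect_equal(dim(imgs), c(16L, 16L, 3L, 3L))
  expect_true(all(imgs >= 0 & imgs <= 255))
  expect_identical(imgs, synthesize(fit$generator, 3, seed = 7))
  expect_false(identical(imgs, synthesize(fit$generator, 3, seed = 8)))
  expect_error(synthesize(fit$generator, 0), "n must be")
})

test_that("one-network updates leave the other network's weights fixed", {
  set.seed(6)
  cfg <- gan_config(image_size = 16L, batch_size = 4L, seed = 6L)
  gen <- build_generator(cfg)
  disc <- build_discriminator(cfg)
  opt_d <- make_optimizer("adam", 1e-3)
  before_g <- lapply(gen$params, function(p) p$value)
  # a pure discriminator step: forward fakes, backward, step D only
  z <- matrix(rnorm(4 * 100), 4)
  fake <- gen$forward(z, training = TRUE)
  logits <- disc$forward(fake, training = TRUE)
  p <- 1 / (1 + exp(-logits))
  zero_grads(disc$params); zero_grads(gen$params)
  disc$backward(matrix(p - 0, ncol = 1) / 4)
  opt_d$step(disc$params)
  expect_identical(lapply(gen$params, function(p) p$value), before_g)
})

test_that("augmentation plan reproduces the published accounting", {
  plan <- plan_augmentation(
    c(CNV = 37206, DME = 11349, DRUSEN = 8617, NORMAL = 51140),
    c(DME = 8739, DRUSEN = 13598))
  get <- function(cl, col) plan[plan$class == cl, col]
  expect_equal(get("DME", "total_count"), 20088)
  expect_equal(get("DRUSEN", "total_count"), 22215)
  expect_equal(get("TOTAL", "total_count"), 130649)
  expect_equal(get("DME", "gan_training_count"), 2000)
  # accounting identity
  expect_equal(get("TOTAL", "total_count"),
               get("TOTAL", "original_count") + get("TOTAL", "generated_count"))
  # zero generated -> totals equal originals
  p0 <- plan_augmentation(c(CNV = 10, DME = 20))
  expect_equal(p0$total_count, c(10, 20, 30))
  # single class
  p1 <- plan_augmentation(c(DME = 10), c(DME = 5))
  expect_equal(p1[p1$class == "DME", "total_count"], 15)
  expect_error(plan_augmentation(c(DME = -1)), "non-negative")
})
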