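test_that("erosion and median match brute-force oracles on random images", {
  set.seed(101)
  for (i in 1:50) {
    H <- sample(8:16, 1); W <- sample(8:16, 1)
    img <- matrix(as.numeric(sample(0:255, H * W, TRUE)), H, W)
    k <- sample(c(3, 5), 1)
    expect_identical(erode(img, k), erode_oracle(img, k))
    w <- 3
    expect_identical(median_filter(img, w), median_oracle(img, w))
  }
})

test_that("erosion basics: constants, isolated peak, odd-kernel contract", {
  const <- matrix(42, 8, 8)
  expect_identical(erode(const, 3), const)
  expect_identical(median_filter(const, 3), const)
  peak <- matrix(0, 7, 7); peak[4, 4] <- 255
  expect_true(all(erode(peak, 3) == 0))
  expect_error(erode(peak, 4), "odd")
  expect_error(median_filter(peak, 2), "odd")
})

test_that("median removes isolated salt-and-pepper extremes", {
  set.seed(3)
  img <- matrix(100, 12, 12)
  # isolated corruptions, no two adjacent
  pos <- cbind(c(2, 5, 8, 11), c(3, 7, 2, 10))
  img[pos] <- c(0, 255, 255, 0)
  out <- median_filter(img, 3)
  expect_true(all(out == 100))
})

test_that("erosion is anti-extensive and monotone; stages preserve range", {
  set.seed(11)
  for (i in 1:10) {
    a <- matrix(as.numeric(sample(0:255, 100, TRUE)), 10, 10)
    b <- pmin(a + sample(0:30, 100, TRUE), 255)
    expect_true(all(erode(a, 3) <= a))
    expect_true(all(erode(a, 3) <= erode(b, 3)))
    for (out in list(erode(a, 5), median_filter(a, 3),
                     adjust_alpha_beta(a, 1.7, -20)))
      expect_true(all(out >= 0 & out <= 255))
  }
})

test_that("erosion and median commute with constant shifts below saturation", {
  set.seed(12)
  a <- matrix(as.numeric(sample(20:200, 64, TRUE)), 8, 8)
  expect_identical(erode(a + 17, 3), erode(a, 3) + 17)
  expect_identical(median_filter(a + 17, 3), median_filter(a, 3) + 17)
})

test_that("alpha-beta correction evaluates, clips and rejects bad gain", {
  expect_equal(adjust_alpha_beta(matrix(100), 1, 2)[1, 1], 102)
  expect_equal(adjust_alpha_beta(matrix(255), 1, 2)[1, 1], 255)
  expect_equal(adjust_alpha_beta(matrix(50), 2, -10)[1, 1], 90)
  expect_equal(adjust_alpha_beta(matrix(1), 1, -5)[1, 1], 0)
  expect_error(adjust_alpha_beta(matrix(1), 0, 2), "alpha")
  expect_error(preprocess_config(beta = 200), "beta")
})

test_that("white-border removal crops exactly the white margins", {
  img <- render_phantom(phantom_spec("DME", border_width = 10, seed = 21))
  out <- remove_white_border(img)
  expect_equal(dim(out), dim(img) - 20L)
  # no white margins -> unchanged
  dark <- matrix(as.numeric(sample(0:200, 400, TRUE)), 20, 20)
  expect_identical(remove_white_border(dark), dark)
  # single white top row -> exactly that row removed
  topped <- rbind(matrix(255, 1, 20), dark)
  expect_identical(remove_white_border(topped), dark)
  # entirely white image is degenerate
  expect_error(remove_white_border(matrix(255, 5, 5)), "entirely white")
})

test_that("preprocess composes the four stages in order", {
  cfg <- preprocess_config()
  img <- render_phantom(phantom_spec("CNV", border_width = 8, seed = 31))
  chain <- adjust_alpha_beta(
    median_filter(
      erode(remove_white_border(img, cfg), cfg$erosion_kernel),
      cfg$median_window),
    cfg$alpha, cfg$beta)
  expect_identical(preprocess(img, cfg), chain)
  # identity configuration returns the input unchanged
  id <- preprocess_config(erosion_kernel = 1, median_window = 1,
                          alpha = 1, beta = 0)
  dark <- matrix(as.numeric(sample(0:200, 256, TRUE)), 16, 16)
  expect_identical(preprocess(dark, id), dark)
  # final beta stage shifts the unsaturated histogram by +2
  no_beta <- median_filter(erode(remove_white_border(img, cfg), 5), 3)
  shifted <- preprocess(img, cfg)
  sel <- no_beta <= 253
  expect_true(all(shifted[sel] == no_beta[sel] + 2))
})
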