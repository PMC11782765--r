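#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(255^2 / MSE)} for 8-bit images. Identical images have
#' zero MSE and are reported as \code{Inf} (a sentinel, never a number).
#'
#' @param a,b Images of identical geometry (matrix or array), 8-bit scale.
#' @return PSNR in dB, or \code{Inf} for identical inputs.
#' @export
psnr <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("psnr: shape mismatch")
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

gauss_kernel_1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

# Valid-mode separable correlation with a 1-D kernel applied to rows and
# columns, done as two band-matrix products.
filt_valid <- function(x, g) {
  k <- length(g)
  H <- nrow(x); W <- ncol(x)
  Kr <- matrix(0, H - k + 1L, H)
  for (i in seq_len(H - k + 1L)) Kr[i, i:(i + k - 1L)] <- g
  Kc <- matrix(0, W - k + 1L, W)
  for (i in seq_len(W - k + 1L)) Kc[i, i:(i + k - 1L)] <- g
  Kr %*% x %*% t(Kc)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5), stabilizing
#' constants \code{C1 = (0.01 L)^2}, \code{C2 = (0.03 L)^2} for dynamic
#' range \code{L = 255}, Gaussian-weighted (population) moments, evaluated
#' over the valid interior.
#'
#' @param a,b Grayscale images of identical geometry, at least 11 x 11.
#' @return SSIM in \[-1, 1\]; 1 for identical images.
#' @export
ssim <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("ssim: shape mismatch")
  if (length(dim(a)) == 3) { a <- apply(a, c(1, 2), mean); b <- apply(b, c(1, 2), mean) }
  if (nrow(a) < 11 || ncol(a) < 11) stop("ssim: image smaller than the 11x11 window")
  a <- matrix(as.numeric(a), nrow(a)); b <- matrix(as.numeric(b), nrow(b))
  g <- gauss_kernel_1d()
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  mu1 <- filt_valid(a, g); mu2 <- filt_valid(b, g)
  s11 <- filt_valid(a * a, g) - mu1^2
  s22 <- filt_valid(b * b, g) - mu2^2
  s12 <- filt_valid(a * b, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Paired real-vs-synthetic image quality report
#'
#' Samples \code{n_per_side} real and \code{n_per_side} synthetic images
#' per class (seeded, without replacement), pairs them by sampled order
#' (the i-th real with the i-th synthetic), and reports mean PSNR and SSIM
#' per class plus equal-weight overall means. When both sides hold the
#' same number of images the same sampled positions are used on each side,
#' so a directory compared against a copy of itself pairs every image with
#' itself. Identical pairs contribute to \code{n_infinite_psnr} and are
#' excluded from the PSNR mean.
#'
#' @param real_dir,synth_dir Directories, either flat or with one
#'   subdirectory per class (CNV/DME/DRUSEN/NORMAL).
#' @param n_per_side Images sampled on each side per class.
#' @param seed Integer sampling seed.
#' @return List of class \code{quality_report}: \code{per_class}
#'   data.frame (class, n_pairs, mean_psnr, mean_ssim, n_infinite_psnr)
#'   and \code{overall} (mean_psnr, mean_ssim).
#' @export
quality_report <- function(real_dir, synth_dir, n_per_side = 50L, seed = 1L) {
  classes_in <- function(d) {
    sub <- intersect(toupper(list.dirs(d, recursive = FALSE,
                                       full.names = FALSE)), oct_classes())
    if (length(sub)) sub else NA_character_
  }
  cls <- classes_in(real_dir)
  rows <- list()
  with_seed(seed, {
    for (cl in cls) {
      rd <- if (is.na(cl)) real_dir else
        file.path(real_dir, basename(list.dirs(real_dir, recursive = FALSE))[
          toupper(basename(list.dirs(real_dir, recursive = FALSE))) == cl])
      sd <- if (is.na(cl)) synth_dir else
        file.path(synth_dir, basename(list.dirs(synth_dir, recursive = FALSE))[
          toupper(basename(list.dirs(synth_dir, recursive = FALSE))) == cl])
      rf <- sort(list.files(rd, pattern = "\\.(png|pgm|ppm)$",
                            full.names = TRUE, ignore.case = TRUE))
      sf <- sort(list.files(sd, pattern = "\\.(png|pgm|ppm)$",
                            full.names = TRUE, ignore.case = TRUE))
      if (length(rf) < n_per_side || length(sf) < n_per_side)
        stop(sprintf(
          "class %s: need %d images per side, have %d real / %d synthetic",
          ifelse(is.na(cl), "(flat)", cl), n_per_side, length(rf), length(sf)))
      # one positional draw shared by both sides when their counts match,
      # so a copied directory pairs every image with itself
      ir <- sample(length(rf), n_per_side)
      is_ <- if (length(sf) == length(rf)) ir
        else sample(length(sf), n_per_side)
      ri <- rf[ir]
      si <- sf[is_]
      ps <- numeric(n_per_side); ss <- numeric(n_per_side)
      for (i in seq_len(n_per_side)) {
        a <- read_image(ri[i]); b <- read_image(si[i])
        if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
        if (length(dim(b)) == 3) b <- apply(b, c(1, 2), mean)
        if (!identical(dim(a), dim(b)))
          b <- resize(b, dim(a))
        ps[i] <- psnr(a, b); ss[i] <- ssim(a, b)
      }
      fin <- is.finite(ps)
      rows[[length(rows) + 1]] <- data.frame(
        class = ifelse(is.na(cl), "ALL", cl), n_pairs = n_per_side,
        mean_psnr = if (any(fin)) mean(ps[fin]) else NA_real_,
        mean_ssim = mean(ss), n_infinite_psnr = sum(!fin),
        stringsAsFactors = FALSE)
    }
  })
  per_class <- do.call(rbind, rows)
  out <- list(per_class = per_class,
              overall = list(mean_psnr = mean(per_class$mean_psnr),
                             mean_ssim = mean(per_class$mean_ssim)))
  class(out) <- "quality_report"
  out
}
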