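#' Preprocessing configuration
#'
#' Parameters for the four-stage OCT enhancement chain: white-border
#' removal, morphological erosion, median filtering and alpha-beta
#' (gain/bias) correction.
#'
#' @param erosion_kernel Odd side length of the square erosion structuring
#'   element (default 5).
#' @param median_window Odd side length of the median window (default 3).
#' @param alpha Gain (contrast), must be > 0 (default 1).
#' @param beta Bias (brightness) in \[-127, 127\] (default 2).
#' @param border_white_level Intensity at or above which a pixel counts as
#'   "white" for border detection (default 245).
#' @param border_white_fraction Fraction of a margin row/column that must be
#'   white for the line to be cropped (default 0.9).
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(erosion_kernel = 5L, median_window = 3L,
                              alpha = 1, beta = 2,
                              border_white_level = 245,
                              border_white_fraction = 0.9) {
  stopifnot(erosion_kernel >= 1, erosion_kernel %% 2 == 1,
            median_window >= 1, median_window %% 2 == 1,
            alpha > 0, beta >= -127, beta <= 127,
            border_white_fraction > 0, border_white_fraction <= 1)
  structure(list(erosion_kernel = as.integer(erosion_kernel),
                 median_window = as.integer(median_window),
                 alpha = alpha, beta = beta,
                 border_white_level = border_white_level,
                 border_white_fraction = border_white_fraction),
            class = "preprocess_config")
}

check_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a grayscale image matrix")
  invisible(img)
}

#' Remove white borders by cropping
#'
#' Contiguous margin rows/columns in which at least
#' \code{border_white_fraction} of the pixels are at or above
#' \code{border_white_level} are cropped from each edge. The interior is
#' untouched; scanner-export frames disappear, content does not.
#'
#' @param img Grayscale image matrix.
#' @param cfg A [preprocess_config()].
#' @return The cropped image.
#' @export
remove_white_border <- function(img, cfg = preprocess_config()) {
  check_gray(img)
  H <- nrow(img); W <- ncol(img)
  white_row <- function(i) mean(img[i, ] >= cfg$border_white_level) >=
    cfg$border_white_fraction
  white_col <- function(j) mean(img[, j] >= cfg$border_white_level) >=
    cfg$border_white_fraction
  top <- 0L
  while (top < H && white_row(top + 1L)) top <- top + 1L
  if (top == H) stop("degenerate input: image is entirely white")
  bot <- 0L
  while (bot < H - top && white_row(H - bot)) bot <- bot + 1L
  img <- img[(top + 1L):(H - bot), , drop = FALSE]
  H2 <- nrow(img)
  wc <- function(j) mean(img[, j] >= cfg$border_white_level) >=
    cfg$border_white_fraction
  left <- 0L
  while (left < W && wc(left + 1L)) left <- left + 1L
  if (left == W) stop("degenerate input: image is entirely white")
  right <- 0L
  while (right < W - left && wc(W - right)) right <- right + 1L
  img[, (left + 1L):(W - right), drop = FALSE]
}

#' Morphological erosion (grayscale minimum filter)
#'
#' Each output pixel is the minimum of the \code{kernel x kernel}
#' neighborhood centered on it; image edges are handled by replication.
#'
#' @param img Grayscale image matrix.
#' @param kernel Odd structuring-element side length (default 5).
#' @return The eroded image.
#' @export
erode <- function(img, kernel = 5L) {
  check_gray(img)
  if (kernel %% 2 != 1 || kernel < 1) stop("erosion kernel must be odd and >= 1")
  if (kernel == 1) return(img)
  minfilt_cpp(img, as.integer(kernel))
}

#' Median filter
#'
#' Sliding-window median with edge replication; removes impulsive (speckle)
#' noise while preserving edges.
#'
#' @param img Grayscale image matrix.
#' @param window Odd window side length (default 3).
#' @return The filtered image.
#' @export
median_filter <- function(img, window = 3L) {
  check_gray(img)
  if (window %% 2 != 1 || window < 1) stop("median window must be odd and >= 1")
  if (window == 1) return(img)
  medfilt_cpp(img, as.integer(window))
}

#' Alpha-beta (gain/bias) correction
#'
#' Per pixel, \code{p = clip(alpha * f + beta, 0, 255)} rounded half-up to
#' the nearest integer. Alpha scales contrast, beta shifts brightness.
#'
#' @param img Grayscale image matrix.
#' @param alpha Gain > 0.
#' @param beta Bias in \[-127, 127\].
#' @return The corrected image.
#' @export
adjust_alpha_beta <- function(img, alpha = 1, beta = 2) {
  check_gray(img)
  if (alpha <= 0) stop("alpha must be > 0")
  pmin(pmax(floor(alpha * img + beta + 0.5), 0), 255)
}

#' Full preprocessing chain
#'
#' Applies, in order: white-border removal, erosion, median filtering,
#' alpha-beta correction.
#'
#' @param img Grayscale image matrix.
#' @param cfg A [preprocess_config()].
#' @return The enhanced image.
#' @export
preprocess <- function(img, cfg = preprocess_config()) {
  img <- remove_white_border(img, cfg)
  img <- erode(img, cfg$erosion_kernel)
  img <- median_filter(img, cfg$median_window)
  adjust_alpha_beta(img, cfg$alpha, cfg$beta)
}

#' Preprocess an image folder
#'
#' Reads every image under \code{in_dir} (recursively, keeping the relative
#' layout), runs [preprocess()] and writes the result under \code{out_dir}.
#'
#' @param in_dir,out_dir Source and destination directories.
#' @param cfg A [preprocess_config()].
#' @return Invisibly, the number of images processed.
#' @export
preprocess_folder <- function(in_dir, out_dir, cfg = preprocess_config()) {
  files <- list.files(in_dir, pattern = "\\.(png|pgm|ppm)$", recursive = TRUE,
                      ignore.case = TRUE)
  for (f in files) {
    img <- read_image(file.path(in_dir, f))
    if (!is.matrix(img)) img <- img[, , 1]
    out <- preprocess(img, cfg)
    dest <- file.path(out_dir, f)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    write_image(out, dest)
  }
  invisible(length(files))
}
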