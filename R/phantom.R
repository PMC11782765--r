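#' Synthetic retinal OCT phantoms
#'
#' A phantom is a seeded, fully synthetic grayscale image that mimics the
#' gross structure of a retinal OCT B-scan: a stack of horizontal
#' hyper-/hypo-reflective bands (the retinal layers) bowed by a smooth
#' curvature, class-specific lesions, multiplicative speckle noise, and a
#' white frame like the scanner-export borders found in clinical datasets.
#' Phantoms make every stage of the pipeline testable offline; they are not
#' photorealistic OCT simulations.
#'
#' Class effects at default settings:
#' \itemize{
#'   \item \code{NORMAL}: bands only.
#'   \item \code{DRUSEN}: small bright bumps deforming the deepest band
#'     (the RPE line) upward.
#'   \item \code{DME}: dark elliptical intraretinal cavities inside the mid
#'     bands.
#'   \item \code{CNV}: one irregular bright mass below the band stack.
#' }
#'
#' @param label One of \code{"CNV"}, \code{"DME"}, \code{"DRUSEN"},
#'   \code{"NORMAL"}.
#' @param height,width Image size in pixels.
#' @param n_layers Number of horizontal retinal bands.
#' @param curvature Vertical sinusoidal displacement amplitude, pixels.
#' @param lesion_count,lesion_radius Class-lesion parameters; \code{NULL}
#'   picks a per-class default (CNV: 1 mass of radius 26; DME: 5 cavities of
#'   radius 12; DRUSEN: 8 bumps of radius 12; NORMAL: none).
#' @param speckle_sigma Standard deviation of the multiplicative speckle
#'   noise factor (pixel <- pixel * (1 + eps), eps ~ N(0, sigma^2)).
#' @param border_width White frame thickness in pixels.
#' @param seed Integer seed; the same spec renders bit-identical images.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(label, height = 224L, width = 224L, n_layers = 8L,
                         curvature = 8, lesion_count = NULL,
                         lesion_radius = NULL, speckle_sigma = 0.1,
                         border_width = 10L, seed = 1L) {
  label <- toupper(label)
  if (!label %in% oct_classes())
    stop("invalid phantom label '", label, "'; expected one of ",
         paste(oct_classes(), collapse = ", "))
  stopifnot(height > 0, width > 0, n_layers >= 1, speckle_sigma >= 0,
            border_width >= 0, border_width < min(height, width) / 2)
  if (is.null(lesion_count))
    lesion_count <- switch(label, CNV = 1L, DME = 5L, DRUSEN = 8L, NORMAL = 0L)
  if (is.null(lesion_radius)) {
    # stated for 224 x 224; scale down proportionally for smaller renders
    scale <- min(height, width) / 224
    lesion_radius <- switch(label, CNV = 26, DME = 12, DRUSEN = 12,
                            NORMAL = 0) * scale
  }
  structure(list(label = label, height = as.integer(height),
                 width = as.integer(width), n_layers = as.integer(n_layers),
                 curvature = curvature, lesion_count = as.integer(lesion_count),
                 lesion_radius = lesion_radius, speckle_sigma = speckle_sigma,
                 border_width = as.integer(border_width),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' The four OCT class labels
#' @return Character vector \code{c("CNV", "DME", "DRUSEN", "NORMAL")}.
#' @export
oct_classes <- function() c("CNV", "DME", "DRUSEN", "NORMAL")

# Alternating bright/dark band palette spanning [40, 200].
band_palette <- function(n) {
  nb <- ceiling(n / 2); nd <- floor(n / 2)
  bright <- seq(200, 140, length.out = max(nb, 1))
  dark <- seq(70, 40, length.out = max(nd, 1))
  pal <- numeric(n)
  pal[seq(1, n, by = 2)] <- bright[seq_len(nb)]
  if (nd > 0) pal[seq(2, n, by = 2)] <- dark[seq_len(nd)]
  pal
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render a phantom OCT image
#'
#' @param spec A [phantom_spec()].
#' @param noise,border Logical switches to disable the speckle stage or the
#'   white frame (used by re-render invariance tests).
#' @return A \code{height x width} integer-valued matrix in \[0, 255\] with
#'   attribute \code{label}.
#' @export
render_phantom <- function(spec, noise = TRUE, border = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width; n <- spec$n_layers
  with_seed(spec$seed, {
    t0 <- 0.30 * H
    b0 <- 0.72 * H
    th <- (b0 - t0) / n
    xs <- seq_len(W)
    off <- spec$curvature * sin(pi * (xs - 1) / max(W - 1, 1))
    pal <- band_palette(n)
    bg_above <- 12; bg_below <- 5
    Y <- matrix(seq_len(H), H, W)
    OFF <- matrix(off, H, W, byrow = TRUE)
    U <- (Y - OFF - t0) / th
    idx <- floor(U)
    val <- matrix(bg_above, H, W)
    val[idx >= n] <- bg_below
    inside <- idx >= 0 & idx < n
    val[inside] <- pal[idx[inside] + 1]
    # 1-pixel linear blend at each band top for smooth boundaries
    dpix <- (U - idx) * th
    blend <- inside & dpix < 1
    prev <- ifelse(idx > 0, pal[pmax(idx, 1)], bg_above)
    val[blend] <- prev[blend] * (1 - dpix[blend]) + val[blend] * dpix[blend]

    stack_bottom <- t0 + n * th + off   # per column
    XS <- matrix(xs, H, W, byrow = TRUE)
    r <- spec$lesion_radius
    k <- spec$lesion_count
    lesion_x <- function() {
      lo <- r + spec$border_width + 4
      hi <- W - r - spec$border_width - 4
      if (hi <= lo) W / 2 else stats::runif(1, lo, hi)
    }
    if (spec$label == "DRUSEN" && k > 0) {
      for (i in seq_len(k)) {
        cx <- lesion_x()
        yb <- t0 + n * th + spec$curvature * sin(pi * (cx - 1) / max(W - 1, 1))
        m <- ((XS - cx)^2 + (Y - yb)^2 <= r^2) & (Y <= yb)
        val[m] <- 215
      }
    } else if (spec$label == "DME" && k > 0) {
      for (i in seq_len(k)) {
        cx <- lesion_x()
        cy <- t0 + th * stats::runif(1, 0.3 * n, 0.7 * n) +
          spec$curvature * sin(pi * (cx - 1) / max(W - 1, 1))
        m <- ((XS - cx)^2 / (1.4 * r)^2 + (Y - cy)^2 / (0.8 * r)^2) <= 1
        val[m] <- 18
      }
    } else if (spec$label == "CNV" && k > 0) {
      for (i in seq_len(k)) {
        cx <- stats::runif(1, 0.35 * W, 0.65 * W)
        cy <- stats::runif(1, 0.80 * H, 0.88 * H)
        ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
        dx <- XS - cx; dy <- Y - cy
        th_ <- atan2(dy, dx)
        rr <- r * (1 + 0.3 * sin(3 * th_ + ph1) + 0.2 * sin(5 * th_ + ph2))
        m <- (dx^2 + dy^2) <= rr^2
        val[m] <- 190
      }
    }

    if (noise && spec$speckle_sigma > 0) {
      eps <- matrix(stats::rnorm(H * W, 0, spec$speckle_sigma), H, W)
      val <- val * (1 + eps)
    }
    val <- pmin(pmax(round(val), 0), 255)
    if (border && spec$border_width > 0) {
      bw <- spec$border_width
      val[seq_len(bw), ] <- 255
      val[(H - bw + 1):H, ] <- 255
      val[, seq_len(bw)] <- 255
      val[, (W - bw + 1):W] <- 255
    }
    attr(val, "label") <- spec$label
    val
  })
}

#' Render a phantom dataset to disk
#'
#' Writes one subdirectory per class under \code{out_root} (the Mendeley
#' layout \code{root/<CLASS>/<id>.png}) plus a \code{manifest.csv} recording
#' path, label and per-image seed.
#'
#' @param counts_per_class Named integer vector/list (names from
#'   [oct_classes()]); classes not named get zero images.
#' @param base_seed Integer; image i of the dataset uses seed
#'   \code{base_seed + i}.
#' @param out_root Destination directory (created if needed).
#' @param ... Passed to [phantom_spec()] (e.g. \code{height}, \code{width}).
#' @return Invisibly, the manifest \code{data.frame} (path, label, seed).
#' @export
render_dataset <- function(counts_per_class, base_seed, out_root, ...) {
  counts <- unlist(counts_per_class)
  names(counts) <- toupper(names(counts))
  bad <- setdiff(names(counts), oct_classes())
  if (length(bad))
    stop("unknown class names: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("counts must be >= 0")
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_root)) stop("cannot create output directory: ", out_root)
  rows <- list(); i <- 0L
  for (cls in oct_classes()) {
    d <- file.path(out_root, cls)
    dir.create(d, showWarnings = FALSE)
    nc <- if (cls %in% names(counts)) counts[[cls]] else 0L
    for (j in seq_len(nc)) {
      i <- i + 1L
      sd <- as.integer(base_seed + i)
      img <- render_phantom(phantom_spec(cls, seed = sd, ...))
      p <- file.path(d, sprintf("%s_%05d.png", cls, j))
      write_image(img, p)
      rows[[i]] <- data.frame(path = p, label = cls, seed = sd,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
    else data.frame(path = character(), label = character(), seed = integer())
  utils::write.csv(manifest, file.path(out_root, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' In-memory phantom dataset for model training
#'
#' Renders \code{n_per_class} phantoms per class at native resolution,
#' bilinearly resizes each to \code{side x side}, replicates the grayscale
#' channel to 3 channels and scales to \[0, 1\].
#'
#' @param n_per_class Images per class.
#' @param seed Base seed (per-image seeds are \code{seed + i}).
#' @param side Output side length (the classifier ingests 32).
#' @param ... Passed to [phantom_spec()].
#' @return \code{list(x = array(side, side, 3, 4 * n_per_class), y = factor)}.
#' @export
phantom_dataset <- function(n_per_class, seed = 1L, side = 32L, ...) {
  N <- 4L * n_per_class
  x <- array(0, c(side, side, 3L, N))
  y <- character(N)
  i <- 0L
  for (cls in oct_classes()) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      img <- render_phantom(phantom_spec(cls, seed = as.integer(seed + i), ...))
      small <- resize(img, side)
      x[, , , i] <- array(rep(small / 255, 3), c(side, side, 3L))
      y[i] <- cls
    }
  }
  list(x = x, y = factor(y, levels = oct_classes()))
}
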