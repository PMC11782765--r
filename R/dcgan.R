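#' DCGAN configuration
#'
#' Hyperparameters of the class-balancing DCGAN: Adam, learning rate
#' 0.0008, batch size 128, binary cross-entropy, a 100-long standard-normal
#' latent vector and 224 x 224 x 3 output. Per-class epoch defaults follow
#' the published protocol (DME 400, drusen 250), chosen by class size.
#'
#' @param noise_dim Latent vector length.
#' @param image_size Output side length; must be divisible by 16 (the
#'   generator upsamples 4 times from \code{image_size / 16}).
#' @param learning_rate Optimizer learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param loss Adversarial loss (binary cross-entropy).
#' @param optimizer Optimizer name.
#' @param dropout Discriminator dropout rate.
#' @param seed Integer seed.
#' @return An object of class \code{gan_config}.
#' @export
gan_config <- function(noise_dim = 100L, image_size = 224L,
                       learning_rate = 0.0008, batch_size = 128L,
                       epochs = 1L, loss = "binary_crossentropy",
                       optimizer = "adam", dropout = 0.3, seed = 1L) {
  stopifnot(noise_dim >= 1, learning_rate > 0, epochs >= 1, batch_size >= 1,
            image_size >= 16, image_size %% 16 == 0)
  structure(list(noise_dim = as.integer(noise_dim),
                 image_size = as.integer(image_size),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 optimizer = optimizer, dropout = dropout,
                 seed = as.integer(seed)),
            class = "gan_config")
}

#' Generator topology derived from a configuration
#'
#' The latent vector is projected to a \code{b x b x 512} tensor
#' (\code{b = image_size / 16}) and upsampled through four transposed
#' convolutions of widths 256, 128, 64, 32 — each followed by a leaky
#' rectifier and batch normalization, doubling the spatial size — then a
#' final convolution to 3 channels with tanh output. At the default 224
#' this is 14x14x512 -> 28x28x256 -> 56x56x128 -> 112x112x64 -> 224x224x32
#' -> 224x224x3.
#'
#' @param cfg A [gan_config()].
#' @return List with \code{projection}, \code{widths}, \code{sizes}.
#' @export
generator_spec <- function(cfg = gan_config()) {
  b <- cfg$image_size %/% 16L
  list(projection = c(b, b, 512L), widths = c(256L, 128L, 64L, 32L),
       sizes = b * c(2L, 4L, 8L, 16L))
}

#' Discriminator topology
#'
#' Four stride-2 convolution blocks of widths 32, 64, 128, 256, each
#' convolution followed by a leaky rectifier and dropout, then a dense
#' real/fake head.
#'
#' @param cfg A [gan_config()].
#' @return List with \code{widths}, \code{kernel}, \code{stride}.
#' @export
discriminator_spec <- function(cfg = gan_config()) {
  list(widths = c(32L, 64L, 128L, 256L), kernel = 4L, stride = 2L)
}

#' Build the DCGAN generator
#'
#' @param cfg A [gan_config()].
#' @param spec A [generator_spec()]; spatial sizes must double per stage.
#' @return A generator environment: \code{forward(z)} maps an
#'   \code{n x noise_dim} matrix to an \code{S x S x 3 x n} array in
#'   (-1, 1).
#' @export
build_generator <- function(cfg = gan_config(), spec = generator_spec(cfg)) {
  b <- spec$projection[1]
  if (!all(spec$sizes == b * 2^(1:4)))
    stop("inconsistent generator stage sizes: spatial size must double per stage")
  if (spec$sizes[4] != cfg$image_size)
    stop("generator stages do not reach image_size")
  g <- new.env()
  g$cfg <- cfg
  with_seed(cfg$seed, {
    g$proj <- layer_dense(cfg$noise_dim, b * b * 512L, name = "g.proj")
    widths <- c(512L, spec$widths)
    g$stages <- lapply(1:4, function(i) list(
      tconv = layer_tconv2d(widths[i], widths[i + 1], k = 4L, stride = 2L,
                            name = paste0("g.tconv", i)),
      act = layer_activation("leaky_relu", leaky_alpha = 0.2),
      bn = layer_batchnorm(widths[i + 1], name = paste0("g.bn", i))))
    g$out_conv <- layer_conv2d(spec$widths[4], 3L, 3L, 1L, name = "g.out")
    g$out_act <- layer_activation("tanh")
  })
  g$params <- c(g$proj$params,
                do.call(c, lapply(g$stages, function(s)
                  c(s$tconv$params, s$bn$params))),
                g$out_conv$params)
  g$forward <- function(z, training = FALSE) {
    n <- nrow(z)
    h <- t(g$proj$forward(z, training))
    dim(h) <- c(512L, b, b, n)                 # channel-first internally
    for (s in g$stages) {
      h <- s$tconv$forward(h, training)
      h <- s$act$forward(h, training)
      h <- s$bn$forward(h, training)
    }
    y <- g$out_act$forward(g$out_conv$forward(h, training), training)
    aperm(y, c(2, 3, 1, 4))                    # -> public (H, W, 3, N)
  }
  g$backward <- function(d) {
    d <- aperm(d, c(3, 1, 2, 4))
    d <- g$out_conv$backward(g$out_act$backward(d))
    for (s in rev(g$stages)) {
      d <- s$bn$backward(d)
      d <- s$act$backward(d)
      d <- s$tconv$backward(d)
    }
    n <- dim(d)[4]
    g$proj$backward(t(matrix(d, ncol = n)))
  }
  class(g) <- c("gan_generator", "environment")
  g
}

#' Build the DCGAN discriminator
#'
#' @param cfg A [gan_config()].
#' @param spec A [discriminator_spec()].
#' @return A discriminator environment; \code{forward} returns real/fake
#'   logits, [discriminate()] returns probabilities in (0, 1).
#' @export
build_discriminator <- function(cfg = gan_config(),
                                spec = discriminator_spec(cfg)) {
  d <- new.env()
  d$cfg <- cfg
  S <- cfg$image_size
  widths <- c(3L, spec$widths)
  with_seed(cfg$seed + 1L, {
    d$blocks <- lapply(1:4, function(i) list(
      conv = layer_conv2d(widths[i], widths[i + 1], spec$kernel, spec$stride,
                          name = paste0("d.conv", i)),
      act = layer_activation("leaky_relu", leaky_alpha = 0.2),
      drop = layer_dropout(cfg$dropout)))
    feat <- (S %/% 2L^4)^2 * spec$widths[4]
    d$head <- layer_dense(feat, 1L, name = "d.head")
  })
  d$params <- c(do.call(c, lapply(d$blocks, function(bk) bk$conv$params)),
                d$head$params)
  d$forward <- function(x, training = FALSE) {
    dm <- dim(x)
    if (dm[1] != S || dm[2] != S || dm[3] != 3)
      stop("discriminator expects ", S, "x", S, "x3 input")
    x <- aperm(x, c(3, 1, 2, 4))               # channel-first internally
    for (bk in d$blocks) {
      x <- bk$conv$forward(x, training)
      x <- bk$act$forward(x, training)
      x <- bk$drop$forward(x, training)
    }
    d$feat_dim <- dim(x)
    n <- dim(x)[4]
    d$head$forward(t(matrix(x, ncol = n)), training)
  }
  d$backward <- function(dl) {
    dx <- d$head$backward(dl)
    dx <- array(t(dx), d$feat_dim)
    for (bk in rev(d$blocks)) {
      dx <- bk$drop$backward(dx)
      dx <- bk$act$backward(dx)
      dx <- bk$conv$backward(dx)
    }
    aperm(dx, c(2, 3, 1, 4))                   # back to public layout
  }
  class(d) <- c("gan_discriminator", "environment")
  d
}

#' Discriminator probability of "real"
#'
#' @param disc A discriminator from [build_discriminator()].
#' @param images \code{S x S x 3 x n} array in \[-1, 1\].
#' @return Length-n vector of probabilities strictly inside (0, 1).
#' @export
discriminate <- function(disc, images) {
  as.vector(1 / (1 + exp(-disc$forward(images, training = FALSE))))
}

to_gan_range <- function(images) {
  if (max(images) > 1.5) images / 127.5 - 1 else images
}

#' Train the DCGAN adversarially
#'
#' Alternating updates (one discriminator step per generator step): the
#' discriminator maximizes \code{log R(x) + log(1 - R(C(z)))}; the
#' generator uses the non-saturating objective (maximize
#' \code{log R(C(z))}) while the minimax value function is logged.
#'
#' @param images \code{S x S x 3 x N} array of one class, values in
#'   \[0, 255\] (rescaled internally to \[-1, 1\]) or already in \[-1, 1\].
#' @param cfg A [gan_config()].
#' @param steps Number of adversarial steps; default
#'   \code{epochs * floor(N / batch_size)}.
#' @param checkpoint_dir If non-NULL, generator checkpoints are written
#'   there (RDS state files).
#' @param verbose Print progress every 50 steps.
#' @return List with \code{generator}, \code{discriminator} and
#'   \code{history} (per-step \code{d_loss}, \code{g_loss}, \code{value}).
#' @export
train_dcgan <- function(images, cfg = gan_config(), steps = NULL,
                        checkpoint_dir = NULL, verbose = FALSE) {
  dm <- dim(images)
  if (length(dm) != 4 || dm[3] != 3)
    stop("expected an S x S x 3 x N image array")
  N <- dm[4]
  if (N < cfg$batch_size)
    stop("need at least one batch of images (", cfg$batch_size,
         "), got ", N)
  x <- to_gan_range(images)
  gen <- build_generator(cfg)
  disc <- build_discriminator(cfg)
  if (is.null(steps)) steps <- cfg$epochs * (N %/% cfg$batch_size)
  opt_d <- make_optimizer(cfg$optimizer, cfg$learning_rate)
  opt_g <- make_optimizer(cfg$optimizer, cfg$learning_rate)
  nb <- cfg$batch_size
  hist <- data.frame(step = seq_len(steps), d_loss = NA_real_,
                     g_loss = NA_real_, value = NA_real_)
  eps <- 1e-12
  with_seed(cfg$seed + 2L, {
    for (s in seq_len(steps)) {
      ## discriminator step
      idx <- sample.int(N, nb, replace = N < nb)
      real <- x[, , , idx, drop = FALSE]
      z <- matrix(stats::rnorm(nb * cfg$noise_dim), nb)
      fake <- gen$forward(z, training = TRUE)
      batch <- array(c(real, fake), c(dm[1], dm[2], 3L, 2L * nb))
      targets <- c(rep(1, nb), rep(0, nb))
      logits <- disc$forward(batch, training = TRUE)
      p <- 1 / (1 + exp(-logits))
      d_loss <- -mean(targets * log(pmax(p, eps)) +
                        (1 - targets) * log(pmax(1 - p, eps)))
      v <- mean(log(pmax(p[seq_len(nb)], eps))) +
        mean(log(pmax(1 - p[nb + seq_len(nb)], eps)))
      zero_grads(disc$params); zero_grads(gen$params)
      disc$backward(matrix((p - targets) / (2 * nb), ncol = 1))
      opt_d$step(disc$params)
      ## generator step (non-saturating)
      z <- matrix(stats::rnorm(nb * cfg$noise_dim), nb)
      fake <- gen$forward(z, training = TRUE)
      logits <- disc$forward(fake, training = TRUE)
      p <- 1 / (1 + exp(-logits))
      g_loss <- -mean(log(pmax(p, eps)))
      zero_grads(disc$params); zero_grads(gen$params)
      dimg <- disc$backward(matrix((p - 1) / nb, ncol = 1))
      gen$backward(dimg)
      opt_g$step(gen$params)
      zero_grads(disc$params); zero_grads(gen$params)
      hist$d_loss[s] <- d_loss; hist$g_loss[s] <- g_loss; hist$value[s] <- v
      if (verbose && s %% 50 == 0)
        message(sprintf("step %d: d_loss %.3f g_loss %.3f V %.3f",
                        s, d_loss, g_loss, v))
      if (!is.null(checkpoint_dir) && (s == steps || s %% 500 == 0)) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        nm <- if (s == steps) "generator_final.rds"
          else sprintf("generator_%06d.rds", s)
        saveRDS(gan_generator_state(gen), file.path(checkpoint_dir, nm))
      }
    }
  })
  list(generator = gen, discriminator = disc, history = hist)
}

gan_generator_state <- function(gen) {
  list(params = lapply(gen$params, function(p) p$value),
       bn = lapply(gen$stages, function(s)
         list(mean = s$bn$run_mean, var = s$bn$run_var)))
}

gan_generator_restore <- function(gen, state) {
  stopifnot(length(state$params) == length(gen$params))
  for (i in seq_along(gen$params)) gen$params[[i]]$value <- state$params[[i]]
  for (i in seq_along(gen$stages)) {
    gen$stages[[i]]$bn$run_mean <- state$bn[[i]]$mean
    gen$stages[[i]]$bn$run_var <- state$bn[[i]]$var
  }
  invisible(gen)
}

#' Train a discriminator alone on labeled real/fake images
#'
#' Utility for sanity checks: plain binary cross-entropy training of a
#' discriminator on a fixed set of "real" and "fake" images.
#'
#' @param disc A [build_discriminator()] network.
#' @param real,fake \code{S x S x 3 x n} arrays (any 8-bit or \[-1,1\]
#'   scale).
#' @param steps Gradient steps.
#' @param lr Learning rate.
#' @param seed Seed for dropout masks.
#' @return The mean predicted real-probability of \code{real} after
#'   training.
#' @export
train_discriminator <- function(disc, real, fake, steps = 200, lr = 8e-4,
                                seed = 1L) {
  x <- array(c(to_gan_range(real), to_gan_range(fake)),
             c(dim(real)[1:3], dim(real)[4] + dim(fake)[4]))
  t <- c(rep(1, dim(real)[4]), rep(0, dim(fake)[4]))
  opt <- make_optimizer("adam", lr)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      logits <- disc$forward(x, training = TRUE)
      p <- 1 / (1 + exp(-logits))
      zero_grads(disc$params)
      disc$backward(matrix((p - t) / length(t), ncol = 1))
      opt$step(disc$params)
    }
  })
  mean(discriminate(disc, to_gan_range(real)))
}

#' Sample images from a trained generator
#'
#' @param generator A [build_generator()] network (trained or not).
#' @param n Number of images (> 0).
#' @param seed Seed for the latent draws.
#' @param out_dir If non-NULL, images are written there as PNG files.
#' @return \code{S x S x 3 x n} array of 8-bit values in \[0, 255\].
#' @export
synthesize <- function(generator, n, seed = 1L, out_dir = NULL) {
  if (n <= 0) stop("n must be > 0")
  S <- generator$cfg$image_size
  out <- array(0, c(S, S, 3L, n))
  with_seed(seed, {
    chunk <- 16L
    i <- 0L
    while (i < n) {
      m <- min(chunk, n - i)
      z <- matrix(stats::rnorm(m * generator$cfg$noise_dim), m)
      img <- generator$forward(z, training = FALSE)
      out[, , , (i + 1):(i + m)] <- pmin(pmax(round((img + 1) * 127.5), 0), 255)
      i <- i + m
    }
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(n))
      write_image(out[, , , j], file.path(out_dir, sprintf("synth_%05d.png", j)))
  }
  out
}

#' Class-balancing augmentation plan
#'
#' Per-class accounting of original and GAN-generated images: totals per
#' class and the grand total.
#'
#' @param original_counts Named numeric vector of original images per
#'   class.
#' @param generated_counts Named numeric vector of images to synthesize
#'   (classes omitted get 0).
#' @param gan_training_counts Named vector of real images used to train the
#'   per-class GAN; defaults to 2000 for every augmented class (capped at
#'   the class size).
#' @return A \code{data.frame} (class \code{augmentation_plan}) with
#'   columns class, original_count, gan_training_count, generated_count,
#'   total_count, plus a grand-total row.
#' @export
plan_augmentation <- function(original_counts, generated_counts = numeric(),
                              gan_training_counts = NULL) {
  if (any(original_counts < 0) || any(generated_counts < 0))
    stop("counts must be non-negative")
  classes <- names(original_counts)
  gen <- vapply(classes, function(cl)
    if (cl %in% names(generated_counts)) generated_counts[[cl]] else 0, 0)
  gtr <- vapply(classes, function(cl) {
    v <- if (!is.null(gan_training_counts) &&
             cl %in% names(gan_training_counts)) gan_training_counts[[cl]]
      else if (gen[[cl]] > 0) 2000 else 0
    min(v, original_counts[[cl]])
  }, 0)
  df <- data.frame(class = classes,
                   original_count = as.numeric(original_counts),
                   gan_training_count = gtr,
                   generated_count = gen,
                   total_count = as.numeric(original_counts) + gen,
                   stringsAsFactors = FALSE, row.names = NULL)
  total <- data.frame(class = "TOTAL",
                      original_count = sum(df$original_count),
                      gan_training_count = sum(df$gan_training_count),
                      generated_count = sum(df$generated_count),
                      total_count = sum(df$total_count))
  out <- rbind(df, total)
  class(out) <- c("augmentation_plan", "data.frame")
  out
}
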