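# Minimal neural-network core: layers are environments carrying forward(),
# backward() and a list of trainable parameters. Tensors use the layout
# (H, W, C, N); token sequences are (g*N) x e matrices with position fastest.
# All heavy convolution work goes through the Rcpp im2col/col2im kernels and
# base-R matrix products (BLAS).

new_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0   # zero of the same shape class (vector stays vector)
  p$name <- name
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

n_params <- function(params) sum(vapply(params, function(p) length(p$value), 0))

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

same_pad <- function(H, k, s) {
  OH <- ceiling(H / s)
  pad <- max((OH - 1L) * s + k - H, 0L)
  list(out = as.integer(OH), lo = as.integer(pad %/% 2))
}

## ---- activations ------------------------------------------------------------

activation_fns <- function(name, leaky_alpha = 0.3) {
  switch(name,
    relu = list(
      f = function(x) pmax(x, 0),
      df = function(x, y) (x > 0) * 1),
    elu = list(
      f = function(x) pmax(x, 0) + expm1(pmin(x, 0)),
      df = function(x, y) { ex <- exp(pmin(x, 0)); (x > 0) * (1 - ex) + ex }),
    tanh = list(
      f = function(x) tanh(x),
      df = function(x, y) 1 - y^2),
    softplus = list(
      f = function(x) log1p(exp(-abs(x))) + pmax(x, 0),
      df = function(x, y) 1 / (1 + exp(-x))),
    softsign = list(
      f = function(x) x / (1 + abs(x)),
      df = function(x, y) 1 / (1 + abs(x))^2),
    leaky_relu = list(
      f = function(x) pmax(x, 0) + leaky_alpha * pmin(x, 0),
      df = function(x, y) (x > 0) * (1 - leaky_alpha) + leaky_alpha),
    gelu = list(
      f = function(x) x * stats::pnorm(x),
      df = function(x, y) stats::pnorm(x) + x * stats::dnorm(x)),
    sigmoid = list(
      f = function(x) 1 / (1 + exp(-x)),
      df = function(x, y) y * (1 - y)),
    stop("unknown activation: ", name)
  )
}

layer_activation <- function(name, leaky_alpha = 0.3) {
  l <- new.env()
  fns <- activation_fns(name, leaky_alpha)
  l$params <- list()
  l$forward <- function(x, training = FALSE) {
    l$x <- x
    l$y <- fns$f(x)
    l$y
  }
  l$backward <- function(d) {
    g <- d * fns$df(l$x, l$y)
    dim(g) <- dim(l$x) %||% NULL
    g
  }
  l
}

layer_dropout <- function(rate) {
  l <- new.env()
  l$params <- list()
  l$forward <- function(x, training = FALSE) {
    if (!training || rate <= 0) { l$mask <- NULL; return(x) }
    m <- (stats::runif(length(x)) >= rate) / (1 - rate)
    dim(m) <- dim(x) %||% NULL
    l$mask <- m
    x * m
  }
  l$backward <- function(d) if (is.null(l$mask)) d else d * l$mask
  l
}

## ---- dense ------------------------------------------------------------------

layer_dense <- function(d_in, d_out, name = "dense") {
  l <- new.env()
  l$W <- new_param(glorot_uniform(d_in, d_out, c(d_in, d_out)), paste0(name, ".W"))
  l$b <- new_param(numeric(d_out), paste0(name, ".b"))
  l$params <- list(l$W, l$b)
  l$forward <- function(x, training = FALSE) {
    l$x <- x
    sweep(x %*% l$W$value, 2, l$b$value, `+`)
  }
  l$backward <- function(d) {
    l$W$grad <- l$W$grad + crossprod(l$x, d)
    l$b$grad <- l$b$grad + colSums(d)
    d %*% t(l$W$value)
  }
  l
}

## ---- conv / transposed conv -------------------------------------------------

layer_conv2d <- function(c_in, c_out, k, stride = 1L, pad = "same",
                         name = "conv") {
  l <- new.env()
  fan_in <- c_in * k * k; fan_out <- c_out * k * k
  l$W <- new_param(glorot_uniform(fan_in, fan_out, c(c_out, k * k * c_in)),
                   paste0(name, ".W"))
  l$b <- new_param(numeric(c_out), paste0(name, ".b"))
  l$params <- list(l$W, l$b)
  l$forward <- function(x, training = FALSE) {
    dm <- dim(x)                               # (C, H, W, N)
    H <- dm[2]; W <- dm[3]; N <- dm[4]
    stopifnot(dm[1] == c_in)
    py <- same_pad(H, k, stride); px <- same_pad(W, k, stride)
    l$geom <- list(H = H, W = W, N = N, OH = py$out, OW = px$out,
                   pt = py$lo, pl = px$lo)
    cols <- im2col_cpp(x, H, W, c_in, N, k, k, stride, stride,
                       py$lo, px$lo, py$out, px$out)
    l$cols <- cols
    y <- l$W$value %*% cols                    # c_out x (OH*OW*N)
    dim(y) <- c(c_out, py$out, px$out, N)
    y + l$b$value                              # bias recycles along channels
  }
  l$backward <- function(d) {
    g <- l$geom
    dmat <- matrix(d, nrow = c_out)
    l$W$grad <- l$W$grad + tcrossprod(dmat, l$cols)
    l$b$grad <- l$b$grad + rowSums(dmat)
    dcols <- crossprod(l$W$value, dmat)
    col2im_cpp(dcols, g$H, g$W, c_in, g$N, k, k, stride, stride,
               g$pt, g$pl, g$OH, g$OW)
  }
  l
}

# Transposed convolution doubling spatial size (stride 2, kernel k): the
# forward pass is the data-gradient of a stride-2 "same" convolution mapping
# the (2H x 2W) output back to (H x W).
layer_tconv2d <- function(c_in, c_out, k = 4L, stride = 2L, name = "tconv") {
  l <- new.env()
  fan_in <- c_in * k * k; fan_out <- c_out * k * k
  l$W <- new_param(glorot_uniform(fan_in, fan_out, c(c_in, k * k * c_out)),
                   paste0(name, ".W"))
  l$b <- new_param(numeric(c_out), paste0(name, ".b"))
  l$params <- list(l$W, l$b)
  l$forward <- function(x, training = FALSE) {
    dm <- dim(x)                               # (C, H, W, N)
    H <- dm[2]; W <- dm[3]; N <- dm[4]
    stopifnot(dm[1] == c_in)
    OH <- H * stride; OW <- W * stride
    py <- same_pad(OH, k, stride); px <- same_pad(OW, k, stride)
    stopifnot(py$out == H, px$out == W)
    l$geom <- list(H = H, W = W, N = N, OH = OH, OW = OW, pt = py$lo, pl = px$lo)
    xmat <- matrix(x, nrow = c_in)
    l$xmat <- xmat
    cols <- crossprod(l$W$value, xmat)           # (k*k*c_out) x (H*W*N)
    y <- col2im_cpp(cols, OH, OW, c_out, N, k, k, stride, stride,
                    py$lo, px$lo, H, W)
    y + l$b$value
  }
  l$backward <- function(d) {
    g <- l$geom
    dcols <- im2col_cpp(d, g$OH, g$OW, c_out, g$N, k, k, stride, stride,
                        g$pt, g$pl, g$H, g$W)
    l$W$grad <- l$W$grad + tcrossprod(l$xmat, dcols)
    l$b$grad <- l$b$grad + rowSums(matrix(d, nrow = c_out))
    dxmat <- l$W$value %*% dcols
    dim(dxmat) <- c(c_in, g$H, g$W, g$N)
    dxmat
  }
  l
}

## ---- pooling ----------------------------------------------------------------

layer_pool <- function(type = c("max", "average"), k = 3L, stride = 2L) {
  type <- match.arg(type)
  l <- new.env()
  l$params <- list()
  l$forward <- function(x, training = FALSE) {
    dm <- dim(x)                               # (C, H, W, N)
    py <- same_pad(dm[2], k, stride); px <- same_pad(dm[3], k, stride)
    l$dims <- dm
    if (type == "max") {
      r <- maxpool_cpp(x, dm[2], dm[3], dm[1], dm[4], k, k, stride, stride,
                       py$lo, px$lo, py$out, px$out)
      l$idx <- r$idx
    } else {
      r <- avgpool_cpp(x, dm[2], dm[3], dm[1], dm[4], k, k, stride, stride,
                       py$lo, px$lo, py$out, px$out)
      l$cnt <- r$cnt
      l$geom <- list(pt = py$lo, pl = px$lo, OH = py$out, OW = px$out)
    }
    r$out
  }
  l$backward <- function(d) {
    dm <- l$dims
    if (type == "max")
      maxpool_bwd_cpp(d, l$idx, dm[2], dm[3], dm[1], dm[4])
    else {
      g <- l$geom
      avgpool_bwd_cpp(d, l$cnt, dm[2], dm[3], dm[1], dm[4], k, k,
                      stride, stride, g$pt, g$pl, g$OH, g$OW)
    }
  }
  l
}

## ---- normalization ----------------------------------------------------------

layer_batchnorm <- function(C, momentum = 0.99, eps = 1e-3, name = "bn") {
  l <- new.env()
  l$gamma <- new_param(rep(1, C), paste0(name, ".gamma"))
  l$beta <- new_param(numeric(C), paste0(name, ".beta"))
  l$params <- list(l$gamma, l$beta)
  l$run_mean <- numeric(C); l$run_var <- rep(1, C)
  l$forward <- function(x, training = FALSE) {
    dm <- dim(x); l$dims <- dm                  # (C, H, W, N)
    m <- prod(dm[2:4])
    xm <- matrix(x, nrow = C)                   # C x m; ops recycle along C
    if (training) {
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc^2)
      l$run_mean <- momentum * l$run_mean + (1 - momentum) * mu
      l$run_var <- momentum * l$run_var + (1 - momentum) * v * m / max(m - 1, 1)
    } else {
      mu <- l$run_mean; v <- l$run_var
      xc <- xm - mu
    }
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    l$xhat <- xhat; l$inv <- inv; l$m <- m; l$training <- training
    y <- xhat * l$gamma$value + l$beta$value
    dim(y) <- dm
    y
  }
  l$backward <- function(d) {
    dm <- l$dims
    dmat <- matrix(d, nrow = C)
    l$gamma$grad <- l$gamma$grad + rowSums(dmat * l$xhat)
    l$beta$grad <- l$beta$grad + rowSums(dmat)
    dxhat <- dmat * l$gamma$value
    if (isTRUE(l$training)) {
      dx <- (dxhat - rowMeans(dxhat) - l$xhat * rowMeans(dxhat * l$xhat)) * l$inv
    } else {
      dx <- dxhat * l$inv
    }
    dim(dx) <- dm
    dx
  }
  l
}

# Layer normalization over the embedding axis of a (rows x e) matrix.
layer_layernorm <- function(e, eps = 1e-5, name = "ln") {
  l <- new.env()
  l$gamma <- new_param(rep(1, e), paste0(name, ".gamma"))
  l$beta <- new_param(numeric(e), paste0(name, ".beta"))
  l$params <- list(l$gamma, l$beta)
  l$forward <- function(x, training = FALSE) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    l$xhat <- xc * inv
    l$inv <- inv
    sweep(l$xhat, 2, l$gamma$value, `*`) +
      matrix(l$beta$value, nrow(x), e, byrow = TRUE)
  }
  l$backward <- function(d) {
    l$gamma$grad <- l$gamma$grad + colSums(d * l$xhat)
    l$beta$grad <- l$beta$grad + colSums(d)
    dxhat <- sweep(d, 2, l$gamma$value, `*`)
    (dxhat - rowMeans(dxhat) - l$xhat * rowMeans(dxhat * l$xhat)) * l$inv
  }
  l
}

## ---- softmax helpers --------------------------------------------------------

row_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Given p = softmax(z) rowwise and dL/dp, return dL/dz.
softmax_vjp <- function(p, dp) p * (dp - rowSums(dp * p))

## ---- multi-head self-attention ---------------------------------------------

# Tokens enter as a (g*N) x e matrix, position fastest. n_tokens per image is
# carried by the caller.
layer_msa <- function(e, n_heads, dropout = 0.1, name = "msa") {
  stopifnot(e %% n_heads == 0)
  dh <- e / n_heads
  l <- new.env()
  l$Wqkv <- new_param(glorot_uniform(e, 3 * e, c(e, 3 * e)), paste0(name, ".Wqkv"))
  l$bqkv <- new_param(numeric(3 * e), paste0(name, ".bqkv"))
  l$Wo <- new_param(glorot_uniform(e, e, c(e, e)), paste0(name, ".Wo"))
  l$bo <- new_param(numeric(e), paste0(name, ".bo"))
  l$params <- list(l$Wqkv, l$bqkv, l$Wo, l$bo)
  l$drop <- layer_dropout(dropout)
  l$forward <- function(x, training = FALSE, g) {
    N <- nrow(x) / g
    l$x <- x; l$g <- g; l$N <- N
    qkv <- sweep(x %*% l$Wqkv$value, 2, l$bqkv$value, `+`)
    l$cache <- vector("list", N)
    out <- matrix(0, nrow(x), e)
    for (n in seq_len(N)) {
      rows <- ((n - 1) * g + 1):(n * g)
      cc <- vector("list", n_heads)
      for (h in seq_len(n_heads)) {
        ih <- ((h - 1) * dh + 1):(h * dh)
        Q <- qkv[rows, ih, drop = FALSE]
        K <- qkv[rows, e + ih, drop = FALSE]
        V <- qkv[rows, 2 * e + ih, drop = FALSE]
        A <- tcrossprod(Q, K) / sqrt(dh)
        P <- row_softmax(A)
        out[rows, ih] <- P %*% V
        cc[[h]] <- list(Q = Q, K = K, V = V, P = P)
      }
      l$cache[[n]] <- cc
    }
    l$qkv <- qkv
    y <- sweep(out %*% l$Wo$value, 2, l$bo$value, `+`)
    l$out_pre <- out
    l$drop$forward(y, training)
  }
  l$backward <- function(d) {
    d <- l$drop$backward(d)
    l$Wo$grad <- l$Wo$grad + crossprod(l$out_pre, d)
    l$bo$grad <- l$bo$grad + colSums(d)
    dout <- d %*% t(l$Wo$value)
    g <- l$g; N <- l$N
    dqkv <- matrix(0, nrow(l$x), 3 * e)
    for (n in seq_len(N)) {
      rows <- ((n - 1) * g + 1):(n * g)
      for (h in seq_len(n_heads)) {
        ih <- ((h - 1) * dh + 1):(h * dh)
        cc <- l$cache[[n]][[h]]
        dO <- dout[rows, ih, drop = FALSE]
        dP <- tcrossprod(dO, cc$V)
        dV <- crossprod(cc$P, dO)
        dA <- softmax_vjp(cc$P, dP) / sqrt(dh)
        dQ <- dA %*% cc$K
        dK <- crossprod(dA, cc$Q)
        dqkv[rows, ih] <- dQ
        dqkv[rows, e + ih] <- dK
        dqkv[rows, 2 * e + ih] <- dV
      }
    }
    l$Wqkv$grad <- l$Wqkv$grad + crossprod(l$x, dqkv)
    l$bqkv$grad <- l$bqkv$grad + colSums(dqkv)
    dqkv %*% t(l$Wqkv$value)
  }
  l
}

## ---- optimizers -------------------------------------------------------------

make_optimizer <- function(name = c("adam", "adamax", "nadam", "sgd", "rmsprop"),
                           lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  name <- match.arg(name)
  o <- new.env()
  o$name <- name; o$lr <- lr; o$t <- 0L
  o$step <- function(params) {
    o$t <- o$t + 1L
    t <- o$t
    for (p in params) {
      g <- p$grad
      if (is.null(p$opt_m)) { p$opt_m <- g * 0; p$opt_v <- g * 0 }
      if (name == "sgd") {
        p$value <- p$value - lr * g
      } else if (name == "rmsprop") {
        p$opt_v <- 0.9 * p$opt_v + 0.1 * g^2
        p$value <- p$value - lr * g / (sqrt(p$opt_v) + eps)
      } else if (name == "adam") {
        p$opt_m <- beta1 * p$opt_m + (1 - beta1) * g
        p$opt_v <- beta2 * p$opt_v + (1 - beta2) * g^2
        mh <- p$opt_m / (1 - beta1^t)
        vh <- p$opt_v / (1 - beta2^t)
        p$value <- p$value - lr * mh / (sqrt(vh) + eps)
      } else if (name == "adamax") {
        p$opt_m <- beta1 * p$opt_m + (1 - beta1) * g
        p$opt_v <- pmax(beta2 * p$opt_v, abs(g))
        p$value <- p$value - lr / (1 - beta1^t) * p$opt_m / (p$opt_v + eps)
      } else if (name == "nadam") {
        p$opt_m <- beta1 * p$opt_m + (1 - beta1) * g
        p$opt_v <- beta2 * p$opt_v + (1 - beta2) * g^2
        mh <- p$opt_m / (1 - beta1^(t + 1))
        vh <- p$opt_v / (1 - beta2^t)
        p$value <- p$value -
          lr * (beta1 * mh + (1 - beta1) * g / (1 - beta1^t)) / (sqrt(vh) + eps)
      }
    }
    invisible(NULL)
  }
  o
}

## ---- losses -----------------------------------------------------------------

# Losses act on predicted class probabilities p (n x K) against one-hot y.
# value() returns the scalar loss; grad() returns dL/dp (the softmax
# chain rule is applied by the caller via softmax_vjp).
make_loss <- function(name = c("categorical_crossentropy", "binary_crossentropy",
                               "mean_squared_error",
                               "mean_squared_logarithmic_error",
                               "mean_absolute_error")) {
  name <- match.arg(name)
  eps <- 1e-12
  switch(name,
    categorical_crossentropy = list(
      name = name,
      value = function(p, y) -sum(y * log(pmax(p, eps))) / nrow(p),
      grad = function(p, y) -(y / pmax(p, eps)) / nrow(p)),
    binary_crossentropy = list(
      name = name,
      value = function(p, y) {
        -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
      },
      grad = function(p, y) {
        ((1 - y) / pmax(1 - p, eps) - y / pmax(p, eps)) / length(p)
      }),
    mean_squared_error = list(
      name = name,
      value = function(p, y) mean((p - y)^2),
      grad = function(p, y) 2 * (p - y) / length(p)),
    mean_squared_logarithmic_error = list(
      name = name,
      value = function(p, y) mean((log1p(p) - log1p(y))^2),
      grad = function(p, y) 2 * (log1p(p) - log1p(y)) / (1 + p) / length(p)),
    mean_absolute_error = list(
      name = name,
      value = function(p, y) mean(abs(p - y)),
      grad = function(p, y) sign(p - y) / length(p))
  )
}

## ---- sequential container ---------------------------------------------------

nn_sequential <- function(layers) {
  m <- new.env()
  m$layers <- layers
  m$params <- do.call(c, lapply(layers, function(l) l$params))
  m$forward <- function(x, training = FALSE) {
    for (l in m$layers) x <- l$forward(x, training)
    x
  }
  m$backward <- function(d) {
    for (l in rev(m$layers)) d <- l$backward(d)
    d
  }
  m
}

# Serializable snapshot of all parameter values (plus batch-norm running
# statistics), used for checkpointing.
nn_state <- function(model) {
  st <- lapply(model$params, function(p) p$value)
  bn <- lapply(model$layers %||% list(), function(l)
    if (!is.null(l$run_mean)) list(mean = l$run_mean, var = l$run_var))
  list(params = st, bn = bn)
}

nn_restore <- function(model, state) {
  stopifnot(length(state$params) == length(model$params))
  for (i in seq_along(model$params)) {
    stopifnot(length(state$params[[i]]) == length(model$params[[i]]$value))
    model$params[[i]]$value <- state$params[[i]]
  }
  if (!is.null(state$bn) && !is.null(model$layers)) {
    for (i in seq_along(model$layers)) {
      s <- if (i <= length(state$bn)) state$bn[[i]] else NULL
      if (!is.null(s) && !is.null(model$layers[[i]]$run_mean)) {
        model$layers[[i]]$run_mean <- s$mean
        model$layers[[i]]$run_var <- s$var
      }
    }
  }
  invisible(model)
}
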