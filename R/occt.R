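#' OCCT model configuration
#'
#' Hyperparameters of the compact convolutional transformer classifier.
#' Defaults are the tuned configuration: one pre-norm encoder block, a
#' two-stage convolutional tokenizer (3 -> 64 -> 128 channels, kernel 3,
#' stride 1, each stage followed by ReLU and a 3x3 stride-2 pool), token
#' width 128 with 2 attention heads, feed-forward width 384, ELU in the
#' encoder MLP, max pooling, dropout 0.1, no positional embedding, and a
#' 4-class softmax head fed by sequence pooling. Training defaults: Adam,
#' learning rate 0.001, categorical cross-entropy.
#'
#' @param n_blocks Encoder-block count (>= 1).
#' @param tokenizer_kernel Tokenizer convolution kernel side (1..5).
#' @param tokenizer_channels Two-stage tokenizer widths; the second stage
#'   must equal \code{embed_dim}.
#' @param conv_stride Tokenizer convolution stride (1 default; the base
#'   compact-transformer preset uses stride 2 with kernel 4).
#' @param pool \code{"max"} or \code{"average"} (3x3 window, stride 2).
#' @param embed_dim Token width; must be divisible by \code{n_heads}.
#' @param n_heads Attention heads.
#' @param mlp_hidden Feed-forward hidden width.
#' @param dropout Dropout rate on attention and MLP.
#' @param activation Encoder-MLP activation; one of relu, elu, tanh,
#'   softplus, softsign, leaky_relu, gelu, sigmoid. The tokenizer always
#'   uses ReLU.
#' @param n_classes Number of output classes.
#' @param input_size Input image side length (images are side x side x 3).
#' @param optimizer,learning_rate,loss Training-time settings carried with
#'   the architecture because the ablation grid varies them.
#' @param seed Integer seed for weight initialization.
#' @return An object of class \code{occt_config}.
#' @export
occt_config <- function(n_blocks = 1L, tokenizer_kernel = 3L,
                        tokenizer_channels = c(64L, 128L), conv_stride = 1L,
                        pool = c("max", "average"), embed_dim = 128L,
                        n_heads = 2L, mlp_hidden = 384L, dropout = 0.1,
                        activation = "elu", n_classes = 4L, input_size = 32L,
                        optimizer = "adam", learning_rate = 0.001,
                        loss = "categorical_crossentropy", seed = 1L) {
  pool <- match.arg(pool)
  stopifnot(n_blocks >= 1, tokenizer_kernel %in% 1:5,
            embed_dim %% n_heads == 0, length(tokenizer_channels) == 2,
            tokenizer_channels[2] == embed_dim, conv_stride >= 1,
            mlp_hidden >= 1, dropout >= 0, dropout < 1, n_classes >= 2,
            input_size >= 4, learning_rate > 0)
  activation_fns(activation)   # validates the name
  structure(list(n_blocks = as.integer(n_blocks),
                 tokenizer_kernel = as.integer(tokenizer_kernel),
                 tokenizer_channels = as.integer(tokenizer_channels),
                 conv_stride = as.integer(conv_stride), pool = pool,
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 mlp_hidden = as.integer(mlp_hidden), dropout = dropout,
                 activation = activation, n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size), optimizer = optimizer,
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed)),
            class = "occt_config")
}

#' Build the convolutional tokenizer
#'
#' Two convolution stages (3 -> 64 -> embed_dim channels), each a square
#' convolution followed by ReLU and a 3x3 stride-2 pool. Under the stride-1
#' defaults an \code{s x s} input yields \code{(s/4)^2} tokens of width
#' \code{embed_dim}.
#'
#' @param cfg An [occt_config()].
#' @return A layer list usable inside [build_occt()]; its \code{forward}
#'   returns a token matrix with attribute \code{g} (tokens per image).
#' @export
build_tokenizer <- function(cfg) {
  stopifnot(inherits(cfg, "occt_config"))
  if (cfg$tokenizer_kernel > cfg$input_size)
    stop("tokenizer kernel larger than input")
  ch <- cfg$tokenizer_channels
  layers <- list(
    layer_conv2d(3L, ch[1], cfg$tokenizer_kernel, cfg$conv_stride, name = "tok1"),
    layer_activation("relu"),
    layer_pool(cfg$pool, 3L, 2L),
    layer_conv2d(ch[1], ch[2], cfg$tokenizer_kernel, cfg$conv_stride,
                 name = "tok2"),
    layer_activation("relu"),
    layer_pool(cfg$pool, 3L, 2L))
  tok <- new.env()
  tok$layers <- layers
  tok$params <- do.call(c, lapply(layers, function(l) l$params))
  tok$forward <- function(x, training = FALSE) {
    x <- aperm(x, c(3, 1, 2, 4))       # public (H, W, 3, N) -> channel-first
    for (l in layers) x <- l$forward(x, training)
    dm <- dim(x)                       # (e, OH, OW, N)
    tok$out_dim <- dm
    g <- dm[2] * dm[3]
    m <- t(matrix(x, nrow = dm[1]))    # (g*N) x e, position fastest
    attr(m, "g") <- g
    m
  }
  tok$backward <- function(d) {
    dm <- tok$out_dim
    d <- t(d)
    dim(d) <- dm
    for (l in rev(layers)) d <- l$backward(d)
    aperm(d, c(2, 3, 1, 4))
  }
  tok
}

#' Build one pre-norm transformer encoder block
#'
#' \code{x <- x + MSA(LN(x)); x <- x + MLP(LN(x))} with
#' \code{MLP = dense(e -> mlp_hidden) -> activation -> dropout ->
#' dense(mlp_hidden -> e) -> dropout}. With no positional embedding the
#' block is permutation-equivariant over tokens.
#'
#' @param cfg An [occt_config()].
#' @param name Layer-name prefix.
#' @return A block object with \code{forward(x, training, g)} /
#'   \code{backward(d)} over token matrices.
#' @export
build_encoder_block <- function(cfg, name = "blk") {
  stopifnot(inherits(cfg, "occt_config"))
  e <- cfg$embed_dim
  b <- new.env()
  b$ln1 <- layer_layernorm(e, name = paste0(name, ".ln1"))
  b$msa <- layer_msa(e, cfg$n_heads, cfg$dropout, name = paste0(name, ".msa"))
  b$ln2 <- layer_layernorm(e, name = paste0(name, ".ln2"))
  b$fc1 <- layer_dense(e, cfg$mlp_hidden, name = paste0(name, ".fc1"))
  b$act <- layer_activation(cfg$activation)
  b$drop1 <- layer_dropout(cfg$dropout)
  b$fc2 <- layer_dense(cfg$mlp_hidden, e, name = paste0(name, ".fc2"))
  b$drop2 <- layer_dropout(cfg$dropout)
  b$params <- c(b$ln1$params, b$msa$params, b$ln2$params, b$fc1$params,
                b$fc2$params)
  b$forward <- function(x, training = FALSE, g) {
    a <- b$msa$forward(b$ln1$forward(x, training), training, g = g)
    x <- x + a
    h <- b$fc1$forward(b$ln2$forward(x, training), training)
    h <- b$drop1$forward(b$act$forward(h, training), training)
    h <- b$drop2$forward(b$fc2$forward(h, training), training)
    x + h
  }
  b$backward <- function(d) {
    dh <- b$fc2$backward(b$drop2$backward(d))
    dh <- b$act$backward(b$drop1$backward(dh))
    dx2 <- b$ln2$backward(b$fc1$backward(dh))
    d <- d + dx2
    da <- b$msa$backward(d)
    d + b$ln1$backward(da)
  }
  b
}

#' Sequence pooling
#'
#' Attention-style pooling that replaces a class token: a learnable scoring
#' map assigns one logit per token, a softmax over the sequence turns the
#' logits into weights, and the pooled vector is the weighted sum of the
#' tokens. With a zero scoring map this is the token mean; with one token
#' it is the identity.
#'
#' @param tokens A \code{g x e} matrix of token embeddings (one image).
#' @param w Scoring weights, length \code{e}.
#' @param b Scoring bias (scalar).
#' @return A list with \code{pooled} (length-e vector) and \code{weights}
#'   (length-g softmax weights, summing to 1).
#' @export
sequence_pool <- function(tokens, w, b = 0) {
  if (is.null(dim(tokens)) || nrow(tokens) < 1)
    stop("sequence_pool: empty token sequence")
  stopifnot(length(w) == ncol(tokens))
  logits <- as.vector(tokens %*% w) + b
  z <- exp(logits - max(logits))
  wt <- z / sum(z)
  list(pooled = as.vector(crossprod(tokens, wt)), weights = wt)
}

#' Build the OCCT classifier
#'
#' Tokenizer, \code{n_blocks} encoder blocks, final layer normalization,
#' sequence pooling and a dense softmax head. No positional embedding
#' anywhere.
#'
#' @param cfg An [occt_config()].
#' @return An \code{occt_model} environment with \code{forward} (logits),
#'   \code{predict} (probabilities) and \code{params}.
#' @export
build_occt <- function(cfg = occt_config()) {
  stopifnot(inherits(cfg, "occt_config"))
  m <- new.env()
  m$cfg <- cfg
  e <- cfg$embed_dim
  with_seed(cfg$seed, {
    m$tokenizer <- build_tokenizer(cfg)
    m$blocks <- lapply(seq_len(cfg$n_blocks), function(i)
      build_encoder_block(cfg, name = paste0("blk", i)))
    m$final_ln <- layer_layernorm(e, name = "final_ln")
    m$pool_w <- new_param(glorot_uniform(e, 1, c(e, 1)), "seqpool.w")
    m$pool_b <- new_param(0, "seqpool.b")
    m$head <- layer_dense(e, cfg$n_classes, name = "head")
  })
  m$params <- c(m$tokenizer$params,
                do.call(c, lapply(m$blocks, function(b) b$params)),
                m$final_ln$params, list(m$pool_w, m$pool_b), m$head$params)
  m$forward <- function(x, training = FALSE) {
    tk <- m$tokenizer$forward(x, training)
    g <- attr(tk, "g")
    m$g <- g
    N <- nrow(tk) / g
    for (b in m$blocks) tk <- b$forward(tk, training, g = g)
    tk <- m$final_ln$forward(tk, training)
    m$tokens <- tk
    logits <- as.vector(tk %*% m$pool_w$value) + m$pool_b$value
    lm <- matrix(logits, g, N)                 # tokens x images
    lm <- sweep(lm, 2, apply(lm, 2, max))
    ez <- exp(lm)
    wt <- sweep(ez, 2, colSums(ez), `/`)       # g x N softmax weights
    m$wt <- wt
    pooled <- matrix(0, N, e)
    for (n in seq_len(N)) {
      rows <- ((n - 1) * g + 1):(n * g)
      pooled[n, ] <- crossprod(tk[rows, , drop = FALSE], wt[, n])
    }
    m$pooled <- pooled
    m$head$forward(pooled, training)
  }
  m$backward <- function(dlogits) {
    dpooled <- m$head$backward(dlogits)
    g <- m$g; N <- nrow(dpooled)
    dtk <- matrix(0, g * N, e)
    dscore <- numeric(g * N)
    for (n in seq_len(N)) {
      rows <- ((n - 1) * g + 1):(n * g)
      w <- m$wt[, n]
      tkn <- m$tokens[rows, , drop = FALSE]
      dp <- dpooled[n, ]
      dtk[rows, ] <- outer(w, dp)
      dwt <- as.vector(tkn %*% dp)
      ds <- w * (dwt - sum(dwt * w))           # softmax vjp over the g tokens
      dscore[rows] <- ds
    }
    m$pool_w$grad <- m$pool_w$grad + crossprod(m$tokens, dscore)
    m$pool_b$grad <- m$pool_b$grad + sum(dscore)
    dtk <- dtk + outer(dscore, as.vector(m$pool_w$value))
    dtk <- m$final_ln$backward(dtk)
    for (b in rev(m$blocks)) dtk <- b$backward(dtk)
    m$tokenizer$backward(dtk)
  }
  m$predict <- function(x) row_softmax(m$forward(x, training = FALSE))
  class(m) <- c("occt_model", "environment")
  m
}

#' Count trainable parameters
#'
#' Sum of the element counts of every trainable tensor of a model.
#'
#' @param model An \code{occt_model} (or any object with a \code{params}
#'   list of parameter environments).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  as.integer(n_params(model$params))
}

#' The sequential ablation grid
#'
#' Thirty-two configurations over seven studies, each study varying one
#' axis while holding the winners of the earlier studies fixed:
#' encoder blocks \{1, 2, 3\}; tokenizer kernel \{1..5\}; eight activations;
#' max/average pooling; five optimizers; four learning rates; five losses.
#' The winners chain (1 block, kernel 3, elu, max, adam, lr 0.001,
#' categorical cross-entropy) terminates at the default configuration.
#'
#' @param input_size Input side for the generated configs.
#' @return A list of 32 entries, each \code{list(study, axis, value,
#'   config)}.
#' @export
ablation_grid <- function(input_size = 32L) {
  axes <- list(
    list(study = 1L, axis = "n_blocks", values = c(1L, 2L, 3L), winner = 1L),
    list(study = 2L, axis = "tokenizer_kernel", values = 1:5, winner = 3L),
    list(study = 3L, axis = "activation",
         values = c("relu", "elu", "tanh", "softplus", "softsign",
                    "leaky_relu", "gelu", "sigmoid"), winner = "elu"),
    list(study = 4L, axis = "pool", values = c("max", "average"),
         winner = "max"),
    list(study = 5L, axis = "optimizer",
         values = c("adam", "adamax", "nadam", "sgd", "rmsprop"),
         winner = "adam"),
    list(study = 6L, axis = "learning_rate",
         values = c(0.01, 0.001, 0.006, 0.0008), winner = 0.001),
    list(study = 7L, axis = "loss",
         values = c("categorical_crossentropy", "binary_crossentropy",
                    "mean_squared_error", "mean_squared_logarithmic_error",
                    "mean_absolute_error"),
         winner = "categorical_crossentropy"))
  # axis values not yet ablated start from the base preset
  base <- list(n_blocks = 1L, tokenizer_kernel = 3L, activation = "relu",
               pool = "max", optimizer = "adam", learning_rate = 0.001,
               loss = "categorical_crossentropy")
  grid <- list()
  fixed <- base
  for (ax in axes) {
    for (v in ax$values) {
      args <- fixed
      args[[ax$axis]] <- v
      args$input_size <- input_size
      cfg <- do.call(occt_config, args)
      grid[[length(grid) + 1]] <-
        list(study = ax$study, axis = ax$axis, value = v, config = cfg)
    }
    fixed[[ax$axis]] <- ax$winner
  }
  grid
}
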