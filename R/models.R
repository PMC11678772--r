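# The seven network architectures: dense autoencoder (DAE), convolutional
# autoencoder (CAE), U-Net, chunked U-Net, temporal convolutional network
# (TCN), chunked encoder-only transformer, and the quantification MLP.
#
# Every network is a plain list: architecture tag, spec, and a flat named
# list of parameter arrays.  Forward and backward passes are hand-written
# per architecture over the primitives in nn-ops.R / src/nn_kernels.cpp.
# Batches enter as (B x input_len) matrices; conversion networks return
# (B x input_len), the quantification MLP (B x n_outputs).

#' Architecture specification
#'
#' A `model_spec` fully determines a network: identical `(spec, seed)` yield
#' identical initial parameters (Glorot-uniform weights, zero biases).
#'
#' Architectures and their full-scale defaults:
#' \describe{
#'   \item{dae}{dense encoder `input_len -> 2000 -> 200`, reciprocal decoder;
#'     ReLU hidden, linear output.}
#'   \item{cae}{four 1-D conv layers of 16, 32, 64, 128 kernels (size 3,
#'     stride 1, padding 1), reciprocal decoder ending in one channel;
#'     spatial length preserved everywhere.}
#'   \item{unet}{the CAE plus one skip connection concatenating the encoder
#'     32-kernel activation onto the decoder 32-kernel layer input.}
#'   \item{unet_chunks}{the U-Net applied independently to each chunk of a
#'     [chunk_scheme()] partition, outputs concatenated.}
#'   \item{tcn}{three residual temporal blocks of 25, 50, 100 channels
#'     (kernel 2, causal dilations 1, 2, 4, dropout 0.2), then a linear
#'     projection to one channel.}
#'   \item{transformer}{chunk -> linear embedding (chunk_len -> d_model) ->
#'     encoder layers (multi-head self-attention + feed-forward, post-norm,
#'     dropout, no positional encoding) -> linear head (d_model ->
#'     chunk_len) -> unchunk.  Full scale: 46 x 1000 chunks, d_model 512,
#'     6 layers, 8 heads, feed-forward 2048, dropout 0.1.}
#'   \item{quant_mlp}{dense `input_len -> 200 -> n_outputs`; outputs are
#'     concentrations in mM.}
#' }
#'
#' @param architecture one of `"dae"`, `"cae"`, `"unet"`, `"unet_chunks"`,
#'   `"tcn"`, `"transformer"`, `"quant_mlp"`.
#' @param input_len spectrum length fed to the network.
#' @param seed initialization seed.
#' @param ... architecture-specific overrides: `widths` (dae), `channels`,
#'   `kernel_size` (cae/unet/tcn), `scheme` (unet_chunks/transformer),
#'   `dilations`, `dropout` (tcn), `d_model`, `n_layers`, `n_heads`, `d_ff`,
#'   `dropout` (transformer), `hidden`, `n_outputs` (quant_mlp).
#' @export
model_spec <- function(architecture = c("dae", "cae", "unet", "unet_chunks",
                                        "tcn", "transformer", "quant_mlp"),
                       input_len = 46000L, seed = 1L, ...) {
  architecture <- match.arg(architecture)
  over <- list(...)
  base <- switch(architecture,
    dae = list(widths = c(2000L, 200L)),
    cae = ,
    unet = list(channels = c(16L, 32L, 64L, 128L), kernel_size = 3L),
    unet_chunks = list(channels = c(16L, 32L, 64L, 128L), kernel_size = 3L,
                       scheme = chunk_scheme()),
    tcn = list(channels = c(25L, 50L, 100L), kernel_size = 2L,
               dilations = c(1L, 2L, 4L), dropout = 0.2),
    transformer = list(scheme = chunk_scheme(), d_model = 512L,
                       n_layers = 6L, n_heads = 8L, d_ff = 2048L,
                       dropout = 0.1),
    quant_mlp = list(hidden = 200L, n_outputs = 21L))
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stopf("unknown spec field(s) for '%s': %s", architecture,
          paste(unknown, collapse = ", "))
  base[names(over)] <- over
  spec <- c(list(architecture = architecture,
                 input_len = as.integer(input_len),
                 seed = as.integer(seed)), base)
  validate_spec(spec)
  structure(spec, class = "model_spec")
}

validate_spec <- function(spec) {
  pos <- function(x, what) if (any(x <= 0))
    stopf("invalid '%s' for %s: all values must be positive", what,
          spec$architecture)
  pos(spec$input_len, "input_len")
  switch(spec$architecture,
    dae = pos(spec$widths, "widths"),
    cae = ,
    unet = ,
    unet_chunks = pos(spec$channels, "channels"),
    tcn = {
      pos(spec$channels, "channels")
      if (spec$dropout < 0 || spec$dropout >= 1)
        stopf("invalid 'dropout': must be in [0, 1)")
    },
    transformer = {
      pos(c(spec$d_model, spec$n_layers, spec$n_heads, spec$d_ff), "dims")
      if (spec$d_model %% spec$n_heads != 0)
        stopf("embedding dimension %d not divisible by %d heads",
              spec$d_model, spec$n_heads)
      if (spec$dropout < 0 || spec$dropout >= 1)
        stopf("invalid 'dropout': must be in [0, 1)")
    },
    quant_mlp = {
      if (spec$n_outputs < 1) stopf("invalid 'n_outputs': must be >= 1")
      pos(spec$hidden, "hidden")
    })
  chunked <- spec$architecture %in% c("unet_chunks", "transformer")
  if (chunked) {
    need <- spec$scheme$n_chunks * spec$scheme$chunk_len
    if (spec$input_len != need)
      stopf("input_len %d incompatible with %d x %d chunk scheme (requires %d)",
            spec$input_len, spec$scheme$n_chunks, spec$scheme$chunk_len, need)
  }
  invisible(spec)
}

dense_widths <- function(spec) switch(spec$architecture,
  dae = c(spec$input_len, spec$widths, rev(spec$widths)[-1], spec$input_len),
  quant_mlp = c(spec$input_len, spec$hidden, spec$n_outputs))

# channel sequence of the conv-autoencoder trunk, input channel included
cae_channels <- function(spec, skip = FALSE) {
  ch <- spec$channels
  enc <- c(1L, ch)                                  # 1-16-32-64-128
  dec <- c(rev(ch[-length(ch)]), 1L)                # 64-32-16-1 outputs
  ins <- c(enc[-length(enc)], rev(ch))              # inputs per layer
  outs <- c(ch, dec)
  if (skip) {
    # encoder 32-channel activation concatenated onto the decoder layer
    # that outputs 32 channels
    skip_at <- length(ch) + which(dec == ch[2])[1]
    ins[skip_at] <- ins[skip_at] + ch[2]
  }
  list(ins = ins, outs = outs)
}

#' Closed-form parameter count of an architecture
#'
#' Counts weights and biases from the spec alone, without allocating the
#' network (the full-scale DAE alone holds ~185 million parameters).
#'
#' @param spec a [model_spec()].
#' @export
param_count <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$architecture,
    dae = ,
    quant_mlp = {
      w <- dense_widths(spec)
      sum(w[-length(w)] * w[-1]) + sum(w[-1])
    },
    cae = ,
    unet = ,
    unet_chunks = {
      g <- cae_channels(spec, skip = spec$architecture != "cae")
      sum(spec$kernel_size * g$ins * g$outs) + sum(g$outs)
    },
    tcn = {
      cin <- c(1L, spec$channels[-length(spec$channels)])
      cout <- spec$channels
      k <- spec$kernel_size
      conv <- sum(k * cin * cout + cout) + sum(k * cout * cout + cout)
      down <- sum(ifelse(cin != cout, cin * cout + cout, 0))
      proj <- cout[length(cout)] + 1
      conv + down + proj
    },
    transformer = {
      d <- spec$d_model; cl <- spec$scheme$chunk_len
      per_layer <- 4 * (d * d + d) +            # Q, K, V, output projections
        2 * 2 * d +                             # two layer norms
        d * spec$d_ff + spec$d_ff + spec$d_ff * d + d
      cl * d + d + spec$n_layers * per_layer + d * cl + cl
    })
}

#' Build a network from its spec
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases, unit
#' layer-norm gains) under the spec's seed.
#'
#' @param spec a [model_spec()].
#' @return a `fieldlift_net` object.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  params <- with_seed(spec$seed, switch(spec$architecture,
    dae = ,
    quant_mlp = {
      w <- dense_widths(spec)
      out <- list()
      for (i in seq_len(length(w) - 1)) {
        lay <- dense_init(w[i], w[i + 1])
        out[[sprintf("fc%d_W", i)]] <- lay$W
        out[[sprintf("fc%d_b", i)]] <- lay$b
      }
      out
    },
    cae = ,
    unet = ,
    unet_chunks = {
      g <- cae_channels(spec, skip = spec$architecture != "cae")
      out <- list()
      for (i in seq_along(g$ins)) {
        lay <- conv_init(g$ins[i], g$outs[i], spec$kernel_size)
        out[[sprintf("conv%d_W", i)]] <- lay$W
        out[[sprintf("conv%d_b", i)]] <- lay$b
      }
      out
    },
    tcn = {
      cin <- c(1L, spec$channels[-length(spec$channels)])
      out <- list()
      for (i in seq_along(spec$channels)) {
        co <- spec$channels[i]; k <- spec$kernel_size
        l1 <- conv_init(cin[i], co, k); l2 <- conv_init(co, co, k)
        out[[sprintf("blk%d_c1_W", i)]] <- l1$W
        out[[sprintf("blk%d_c1_b", i)]] <- l1$b
        out[[sprintf("blk%d_c2_W", i)]] <- l2$W
        out[[sprintf("blk%d_c2_b", i)]] <- l2$b
        if (cin[i] != co) {
          dn <- conv_init(cin[i], co, 1L)
          out[[sprintf("blk%d_dn_W", i)]] <- dn$W
          out[[sprintf("blk%d_dn_b", i)]] <- dn$b
        }
      }
      proj <- conv_init(spec$channels[length(spec$channels)], 1L, 1L)
      out$proj_W <- proj$W; out$proj_b <- proj$b
      out
    },
    transformer = {
      d <- spec$d_model; cl <- spec$scheme$chunk_len
      out <- list()
      emb <- dense_init(cl, d)
      out$emb_W <- emb$W; out$emb_b <- emb$b
      for (l in seq_len(spec$n_layers)) {
        p <- function(nm) sprintf("l%d_%s", l, nm)
        for (nm in c("q", "k", "v", "o")) {
          lay <- dense_init(d, d)
          out[[p(paste0(nm, "_W"))]] <- lay$W
          out[[p(paste0(nm, "_b"))]] <- lay$b
        }
        ln1 <- layernorm_init(d); ln2 <- layernorm_init(d)
        out[[p("ln1_g")]] <- ln1$g; out[[p("ln1_b")]] <- ln1$b
        f1 <- dense_init(d, spec$d_ff); f2 <- dense_init(spec$d_ff, d)
        out[[p("ff1_W")]] <- f1$W; out[[p("ff1_b")]] <- f1$b
        out[[p("ff2_W")]] <- f2$W; out[[p("ff2_b")]] <- f2$b
        out[[p("ln2_g")]] <- ln2$g; out[[p("ln2_b")]] <- ln2$b
      }
      head <- dense_init(d, cl)
      out$head_W <- head$W; out$head_b <- head$b
      out
    }))
  structure(list(architecture = spec$architecture, spec = spec,
                 params = params),
            class = c(paste0("net_", spec$architecture), "fieldlift_net"))
}

#' @export
print.fieldlift_net <- function(x, ...) {
  cat(sprintf("<fieldlift_net:%s> input_len %d, %s parameters\n",
              x$architecture, x$spec$input_len,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' @rdname param_count
#' @param net a built network.
#' @export
n_params <- function(net) sum(vapply(net$params, length, 0L))

#' Convenience builders for the individual architectures
#'
#' Thin wrappers over [model_spec()] + [build_network()] with the
#' architecture fixed.
#'
#' @param input_len spectrum length.
#' @param seed initialization seed.
#' @param ... spec overrides, see [model_spec()].
#' @export
build_dae <- function(input_len = 46000L, seed = 1L, ...)
  build_network(model_spec("dae", input_len, seed, ...))

#' @rdname build_dae
#' @export
build_cae <- function(input_len = 46000L, seed = 1L, ...)
  build_network(model_spec("cae", input_len, seed, ...))

#' @rdname build_dae
#' @param chunked apply the U-Net independently per chunk (the
#'   "UNet-Chunks" variant).
#' @export
build_unet <- function(input_len = 46000L, seed = 1L, chunked = FALSE, ...)
  build_network(model_spec(if (chunked) "unet_chunks" else "unet",
                           input_len, seed, ...))

#' @rdname build_dae
#' @export
build_tcn <- function(input_len = 46000L, seed = 1L, ...)
  build_network(model_spec("tcn", input_len, seed, ...))

#' @rdname build_dae
#' @export
build_transformer <- function(input_len = 46000L, seed = 1L, ...)
  build_network(model_spec("transformer", input_len, seed, ...))

#' @rdname build_dae
#' @export
build_quant_mlp <- function(input_len = 46000L, seed = 1L, ...)
  build_network(model_spec("quant_mlp", input_len, seed, ...))

# ---- forward / backward ----------------------------------------------------

net_forward <- function(net, X, training = FALSE) {
  switch(net$architecture,
    dae = ,
    quant_mlp = fwd_dense(net, X),
    cae = fwd_cae(net, X, skip = FALSE),
    unet = fwd_cae(net, X, skip = TRUE),
    unet_chunks = {
      scheme <- net$spec$scheme
      Tk <- tokens_of_batch(X, scheme)
      r <- fwd_cae(net, Tk, skip = TRUE)
      r$tok_B <- nrow(X)
      r$Y <- batch_of_tokens(r$Y, scheme, nrow(X))
      r
    },
    tcn = fwd_tcn(net, X, training),
    transformer = fwd_transformer(net, X, training))
}

net_backward <- function(net, cache, dY) {
  switch(net$architecture,
    dae = ,
    quant_mlp = bwd_dense(net, cache, dY),
    cae = bwd_cae(net, cache, dY, skip = FALSE),
    unet = bwd_cae(net, cache, dY, skip = TRUE),
    unet_chunks = {
      scheme <- net$spec$scheme
      dTk <- tokens_of_batch(dY, scheme)
      bwd_cae(net, cache, dTk, skip = TRUE)
    },
    tcn = bwd_tcn(net, cache, dY),
    transformer = bwd_transformer(net, cache, dY))
}

#' Run a network in inference mode
#'
#' Dropout is disabled; the input batch is processed in sub-batches.
#'
#' @param object a `fieldlift_net`.
#' @param newdata matrix (samples x input_len) or a single spectrum vector.
#' @param batch_size sub-batch size.
#' @param ... unused.
#' @export
predict.fieldlift_net <- function(object, newdata, batch_size = 32L, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$spec$input_len)
    stopf("dimension mismatch: network expects input_len %d, got %d",
          object$spec$input_len, ncol(newdata))
  out <- NULL
  for (s in seq(1, nrow(newdata), by = batch_size)) {
    e <- min(s + batch_size - 1, nrow(newdata))
    y <- net_forward(object, newdata[s:e, , drop = FALSE], training = FALSE)$Y
    if (is.null(out)) out <- matrix(0, nrow(newdata), ncol(y))
    out[s:e, ] <- y
  }
  out
}

# ---- dense stack (DAE, quantification MLP) ---------------------------------

fwd_dense <- function(net, X) {
  w <- dense_widths(net$spec)
  n_lay <- length(w) - 1
  A <- vector("list", n_lay + 1)
  A[[1]] <- X
  for (i in seq_len(n_lay)) {
    Z <- dense_fwd(A[[i]], net$params[[sprintf("fc%d_W", i)]],
                   net$params[[sprintf("fc%d_b", i)]])
    A[[i + 1]] <- if (i < n_lay) relu_fwd(Z) else Z
  }
  list(Y = A[[n_lay + 1]], A = A)
}

bwd_dense <- function(net, cache, dY) {
  w <- dense_widths(net$spec)
  n_lay <- length(w) - 1
  grads <- list()
  dZ <- dY
  for (i in rev(seq_len(n_lay))) {
    W <- net$params[[sprintf("fc%d_W", i)]]
    g <- dense_bwd(cache$A[[i]], W, dZ)
    grads[[sprintf("fc%d_W", i)]] <- g$dW
    grads[[sprintf("fc%d_b", i)]] <- g$db
    if (i > 1) dZ <- relu_bwd(g$dX, cache$A[[i]])
  }
  grads
}

# ---- convolutional autoencoder / U-Net -------------------------------------

same_offsets <- function(k) as.integer(seq_len(k) - 1 - (k - 1) %/% 2)

fwd_cae <- function(net, X, skip) {
  spec <- net$spec
  B <- nrow(X); L <- ncol(X)
  off <- same_offsets(spec$kernel_size)
  g <- cae_channels(spec, skip = skip)
  n_lay <- length(g$ins)
  n_enc <- length(spec$channels)
  skip_at <- if (skip) n_enc + which(c(rev(spec$channels[-n_enc]), 1L) ==
                                       spec$channels[2])[1] else 0L
  A <- vector("list", n_lay + 1)
  A[[1]] <- stack_batch(X)
  for (i in seq_len(n_lay)) {
    inp <- A[[i]]
    if (i == skip_at) inp <- cbind(inp, A[[2 + 1]])  # encoder 32-ch activation
    A[[i + 1]] <- cpp_conv1d_fwd(inp, net$params[[sprintf("conv%d_W", i)]],
                                 net$params[[sprintf("conv%d_b", i)]], off,
                                 B, L, relu = i < n_lay)
  }
  list(Y = unstack_batch(A[[n_lay + 1]], B, L), A = A, B = B, L = L,
       skip_at = skip_at)
}

bwd_cae <- function(net, cache, dY, skip) {
  spec <- net$spec
  B <- cache$B; L <- cache$L
  off <- same_offsets(spec$kernel_size)
  n_lay <- length(cae_channels(spec, skip = skip)$ins)
  grads <- list()
  dZ <- stack_batch(dY)      # gradient w.r.t. each layer output, ReLU-masked
  d_skip <- NULL             # inside the conv backward via Yact
  for (i in rev(seq_len(n_lay))) {
    inp <- cache$A[[i]]
    if (i == cache$skip_at) inp <- cbind(inp, cache$A[[3]])
    g <- cpp_conv1d_bwd(inp, net$params[[sprintf("conv%d_W", i)]], dZ,
                        off, B, L,
                        Yact = if (i < n_lay) cache$A[[i + 1]] else NULL)
    grads[[sprintf("conv%d_W", i)]] <- g$dW
    grads[[sprintf("conv%d_b", i)]] <- as.numeric(g$db)
    dA <- g$dX
    if (i == cache$skip_at) {
      main_ch <- ncol(cache$A[[i]])
      d_skip <- dA[, -(seq_len(main_ch)), drop = FALSE]
      dA <- dA[, seq_len(main_ch), drop = FALSE]
    }
    if (i == 3 && !is.null(d_skip)) dA <- dA + d_skip
    dZ <- dA
  }
  grads
}

# ---- temporal convolutional network ----------------------------------------

fwd_tcn <- function(net, X, training) {
  spec <- net$spec
  B <- nrow(X); L <- ncol(X)
  cin <- c(1L, spec$channels[-length(spec$channels)])
  blocks <- vector("list", length(spec$channels))
  A <- stack_batch(X)
  for (i in seq_along(spec$channels)) {
    off <- c(0L, -spec$dilations[i] * (spec$kernel_size - 1L):1L)
    cb <- list(inp = A, off = off)
    r1 <- cpp_conv1d_fwd(A, net$params[[sprintf("blk%d_c1_W", i)]],
                         net$params[[sprintf("blk%d_c1_b", i)]], off, B, L,
                         relu = TRUE)
    d1 <- dropout_fwd(r1, spec$dropout, training)
    r2 <- cpp_conv1d_fwd(d1$Y, net$params[[sprintf("blk%d_c2_W", i)]],
                         net$params[[sprintf("blk%d_c2_b", i)]], off, B, L,
                         relu = TRUE)
    d2 <- dropout_fwd(r2, spec$dropout, training)
    res <- if (cin[i] != spec$channels[i])
      cpp_conv1d_fwd(A, net$params[[sprintf("blk%d_dn_W", i)]],
                     net$params[[sprintf("blk%d_dn_b", i)]], 0L, B, L)
    else A
    out <- relu_fwd(d2$Y + res)
    cb$r1 <- r1; cb$m1 <- d1$mask; cb$d1 <- d1$Y
    cb$r2 <- r2; cb$m2 <- d2$mask; cb$out <- out
    blocks[[i]] <- cb
    A <- out
  }
  Yst <- cpp_conv1d_fwd(A, net$params$proj_W, net$params$proj_b, 0L, B, L)
  list(Y = unstack_batch(Yst, B, L), blocks = blocks, top = A, B = B, L = L)
}

bwd_tcn <- function(net, cache, dY) {
  spec <- net$spec
  B <- cache$B; L <- cache$L
  cin <- c(1L, spec$channels[-length(spec$channels)])
  grads <- list()
  dZ <- stack_batch(dY)
  g <- cpp_conv1d_bwd(cache$top, net$params$proj_W, dZ, 0L, B, L)
  grads$proj_W <- g$dW; grads$proj_b <- as.numeric(g$db)
  dA <- g$dX
  for (i in rev(seq_along(spec$channels))) {
    cb <- cache$blocks[[i]]
    dSum <- relu_bwd(dA, cb$out)
    # residual branch
    if (cin[i] != spec$channels[i]) {
      gd <- cpp_conv1d_bwd(cb$inp, net$params[[sprintf("blk%d_dn_W", i)]],
                           dSum, 0L, B, L)
      grads[[sprintf("blk%d_dn_W", i)]] <- gd$dW
      grads[[sprintf("blk%d_dn_b", i)]] <- as.numeric(gd$db)
      dInp <- gd$dX
    } else dInp <- dSum
    # main branch (ReLU backward fused into the conv backward via Yact)
    dR2 <- dropout_bwd(dSum, cb$m2)
    g2 <- cpp_conv1d_bwd(cb$d1, net$params[[sprintf("blk%d_c2_W", i)]],
                         dR2, cb$off, B, L, Yact = cb$r2)
    grads[[sprintf("blk%d_c2_W", i)]] <- g2$dW
    grads[[sprintf("blk%d_c2_b", i)]] <- as.numeric(g2$db)
    dR1 <- dropout_bwd(g2$dX, cb$m1)
    g1 <- cpp_conv1d_bwd(cb$inp, net$params[[sprintf("blk%d_c1_W", i)]],
                         dR1, cb$off, B, L, Yact = cb$r1)
    grads[[sprintf("blk%d_c1_W", i)]] <- g1$dW
    grads[[sprintf("blk%d_c1_b", i)]] <- as.numeric(g1$db)
    dA <- dInp + g1$dX
  }
  grads
}

# ---- chunked encoder-only transformer --------------------------------------

fwd_transformer <- function(net, X, training) {
  spec <- net$spec
  scheme <- spec$scheme
  B <- nrow(X); Tn <- scheme$n_chunks
  d <- spec$d_model; H <- spec$n_heads; dh <- d %/% H
  p <- net$params
  drop_p <- if (training) spec$dropout else 0
  Tk <- tokens_of_batch(X, scheme)
  E <- dense_fwd(Tk, p$emb_W, p$emb_b)
  layers <- vector("list", spec$n_layers)
  for (l in seq_len(spec$n_layers)) {
    nm <- function(s) sprintf("l%d_%s", l, s)
    lc <- list(E_in = E)
    Q <- dense_fwd(E, p[[nm("q_W")]], p[[nm("q_b")]])
    K <- dense_fwd(E, p[[nm("k_W")]], p[[nm("k_b")]])
    V <- dense_fwd(E, p[[nm("v_W")]], p[[nm("v_b")]])
    Z <- matrix(0, nrow(E), d)
    Aarr <- array(0, c(Tn, Tn, B, H))
    Marr <- if (drop_p > 0) array(0, c(Tn, Tn, B, H)) else NULL
    for (b in seq_len(B)) {
      idx <- (b - 1) * Tn + seq_len(Tn)
      for (h in seq_len(H)) {
        hc <- (h - 1) * dh + seq_len(dh)
        S <- tcrossprod(Q[idx, hc, drop = FALSE],
                        K[idx, hc, drop = FALSE]) / sqrt(dh)
        A <- softmax_rows(S)
        Ad <- A
        if (drop_p > 0) {
          m <- cpp_dropout_mask(Tn * Tn, drop_p); dim(m) <- c(Tn, Tn)
          Ad <- A * m; Marr[, , b, h] <- m
        }
        Aarr[, , b, h] <- A
        Z[idx, hc] <- Ad %*% V[idx, hc, drop = FALSE]
      }
    }
    O <- dense_fwd(Z, p[[nm("o_W")]], p[[nm("o_b")]])
    dO <- dropout_fwd(O, drop_p, training)
    ln1 <- layernorm_fwd(E + dO$Y, p[[nm("ln1_g")]], p[[nm("ln1_b")]])
    E1 <- ln1$Y
    F1 <- relu_fwd(dense_fwd(E1, p[[nm("ff1_W")]], p[[nm("ff1_b")]]))
    dF1 <- dropout_fwd(F1, drop_p, training)
    F2 <- dense_fwd(dF1$Y, p[[nm("ff2_W")]], p[[nm("ff2_b")]])
    dF2 <- dropout_fwd(F2, drop_p, training)
    ln2 <- layernorm_fwd(E1 + dF2$Y, p[[nm("ln2_g")]], p[[nm("ln2_b")]])
    lc$Q <- Q; lc$K <- K; lc$V <- V; lc$A <- Aarr; lc$M <- Marr; lc$Z <- Z
    lc$mO <- dO$mask; lc$ln1 <- ln1; lc$E1 <- E1
    lc$F1 <- F1; lc$mF1 <- dF1$mask; lc$mF2 <- dF2$mask; lc$ln2 <- ln2
    layers[[l]] <- lc
    E <- ln2$Y
  }
  Ytok <- dense_fwd(E, p$head_W, p$head_b)
  list(Y = batch_of_tokens(Ytok, scheme, B), E_top = E, layers = layers,
       Tk = Tk, B = B)
}

bwd_transformer <- function(net, cache, dY) {
  spec <- net$spec
  scheme <- spec$scheme
  B <- cache$B; Tn <- scheme$n_chunks
  d <- spec$d_model; H <- spec$n_heads; dh <- d %/% H
  p <- net$params
  grads <- list()
  dYtok <- tokens_of_batch(dY, scheme)
  g <- dense_bwd(cache$E_top, p$head_W, dYtok)
  grads$head_W <- g$dW; grads$head_b <- g$db
  dE <- g$dX
  for (l in rev(seq_len(spec$n_layers))) {
    nm <- function(s) sprintf("l%d_%s", l, s)
    lc <- cache$layers[[l]]
    # feed-forward sublayer (post-norm)
    l2 <- layernorm_bwd(lc$ln2, p[[nm("ln2_g")]], dE)
    grads[[nm("ln2_g")]] <- l2$dg; grads[[nm("ln2_b")]] <- l2$db
    dE1 <- l2$dX
    dF2 <- dropout_bwd(l2$dX, lc$mF2)
    g2 <- dense_bwd(if (is.null(lc$mF1)) lc$F1 else lc$F1 * lc$mF1,
                    p[[nm("ff2_W")]], dF2)
    grads[[nm("ff2_W")]] <- g2$dW; grads[[nm("ff2_b")]] <- g2$db
    dF1 <- dropout_bwd(g2$dX, lc$mF1)
    dZ1 <- relu_bwd(dF1, lc$F1)
    g1 <- dense_bwd(lc$E1, p[[nm("ff1_W")]], dZ1)
    grads[[nm("ff1_W")]] <- g1$dW; grads[[nm("ff1_b")]] <- g1$db
    dE1 <- dE1 + g1$dX
    # attention sublayer
    l1 <- layernorm_bwd(lc$ln1, p[[nm("ln1_g")]], dE1)
    grads[[nm("ln1_g")]] <- l1$dg; grads[[nm("ln1_b")]] <- l1$db
    dE <- l1$dX
    dOd <- dropout_bwd(l1$dX, lc$mO)
    go <- dense_bwd(lc$Z, p[[nm("o_W")]], dOd)
    grads[[nm("o_W")]] <- go$dW; grads[[nm("o_b")]] <- go$db
    dZ <- go$dX
    dQ <- matrix(0, nrow(dZ), d); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      idx <- (b - 1) * Tn + seq_len(Tn)
      for (h in seq_len(H)) {
        hc <- (h - 1) * dh + seq_len(dh)
        A <- lc$A[, , b, h]
        m <- if (is.null(lc$M)) NULL else lc$M[, , b, h]
        Ad <- if (is.null(m)) A else A * m
        dZh <- dZ[idx, hc, drop = FALSE]
        Vh <- lc$V[idx, hc, drop = FALSE]
        dAd <- tcrossprod(dZh, Vh)
        dV[idx, hc] <- crossprod(Ad, dZh)
        dA <- if (is.null(m)) dAd else dAd * m
        dS <- softmax_rows_bwd(dA, A) / sqrt(dh)
        dQ[idx, hc] <- dS %*% lc$K[idx, hc, drop = FALSE]
        dK[idx, hc] <- crossprod(dS, lc$Q[idx, hc, drop = FALSE])
      }
    }
    for (pr in list(c("q", "Q"), c("k", "K"), c("v", "V"))) {
      gg <- dense_bwd(lc$E_in, p[[nm(paste0(pr[1], "_W"))]],
                      get(paste0("d", pr[2])))
      grads[[nm(paste0(pr[1], "_W"))]] <- gg$dW
      grads[[nm(paste0(pr[1], "_b"))]] <- gg$db
      dE <- dE + gg$dX
    }
  }
  gE <- dense_bwd(cache$Tk, p$emb_W, dE)
  grads$emb_W <- gE$dW; grads$emb_b <- gE$db
  grads
}
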