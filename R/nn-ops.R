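# Primitive network operations (R side).  Convolution/ReLU/dropout kernels
# live in src/nn_kernels.cpp; dense algebra goes straight to BLAS.

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

dense_init <- function(n_in, n_out)
  list(W = glorot(n_in, n_out), b = numeric(n_out))

dense_fwd <- function(X, W, b) sweep(X %*% W, 2, b, "+")

# returns list(dX, dW, db)
dense_bwd <- function(X, W, dY)
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))

conv_init <- function(cin, cout, k)
  list(W = glorot(cin * k, cout * k, dims = c(k * cin, cout)),
       b = numeric(cout))

relu_fwd <- function(X) cpp_relu_fwd(X)
relu_bwd <- function(dY, Y) cpp_relu_bwd(dY, Y)

dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  cpp_dropout_fwd(X, p)
}

dropout_bwd <- function(dY, mask)
  if (is.null(mask)) dY else cpp_elemmul(dY, mask)

LN_EPS <- 1e-5

layernorm_init <- function(d) list(g = rep(1, d), b = numeric(d))

# row-wise layer normalization over features
layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(Y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dY) {
  dxhat <- sweep(dY, 2, g, "*")
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

softmax_rows_bwd <- function(dA, A) A * (dA - rowSums(dA * A))

#' Mean squared error
#'
#' Mean over all elements of the squared difference.  The training objective
#' for every network in the package and the conversion evaluation metric.
#'
#' @param pred,target numeric vectors/matrices of identical shape.
#' @export
mse_loss <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stopf("shape mismatch: pred is %s, target is %s",
          paste(dim(pred) %||% length(pred), collapse = "x"),
          paste(dim(target) %||% length(target), collapse = "x"))
  mean((pred - target)^2)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  zero <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = zero, v = zero)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  list(opt = opt, params = params)
}

# ---- chunking --------------------------------------------------------------

#' Chunk scheme: contiguous partition of a spectrum into equal bins
#'
#' The chunked transformer and chunked U-Net treat a spectrum as a sequence
#' of `n_chunks` contiguous bins of `chunk_len` points (46 x 1000 at full
#' scale).
#'
#' @param n_chunks,chunk_len partition geometry.
#' @export
chunk_scheme <- function(n_chunks = 46L, chunk_len = 1000L) {
  stopifnot(n_chunks >= 1, chunk_len >= 1)
  structure(list(n_chunks = as.integer(n_chunks),
                 chunk_len = as.integer(chunk_len)),
            class = "chunk_scheme")
}

#' Partition a spectrum into contiguous chunks
#'
#' @param x numeric vector of length `n_chunks * chunk_len`.
#' @param scheme a [chunk_scheme()].
#' @return `chunk_spectrum`: matrix with `n_chunks` rows (one chunk per row,
#'   order preserved).  `unchunk_spectrum` is its exact inverse.
#' @export
chunk_spectrum <- function(x, scheme = chunk_scheme()) {
  need <- scheme$n_chunks * scheme$chunk_len
  if (length(x) != need)
    stopf("cannot chunk length %d: scheme %d x %d requires length %d",
          length(x), scheme$n_chunks, scheme$chunk_len, need)
  t(matrix(x, nrow = scheme$chunk_len))
}

#' @param chunks matrix as returned by `chunk_spectrum`.
#' @rdname chunk_spectrum
#' @export
unchunk_spectrum <- function(chunks) as.vector(t(chunks))

# (B, L) batch -> stacked sample-major (B*L, 1) and back
stack_batch <- function(X) matrix(as.vector(t(X)), ncol = 1)
unstack_batch <- function(y, B, L) t(matrix(y, nrow = L, ncol = B))

# (B, n_chunks*chunk_len) batch -> token matrix (B*n_chunks, chunk_len),
# sample-major, chunk order preserved within each sample
tokens_of_batch <- function(X, scheme) {
  B <- nrow(X)
  out <- matrix(0, B * scheme$n_chunks, scheme$chunk_len)
  for (b in seq_len(B))
    out[(b - 1) * scheme$n_chunks + seq_len(scheme$n_chunks), ] <-
      chunk_spectrum(X[b, ], scheme)
  out
}

batch_of_tokens <- function(Tk, scheme, B) {
  out <- matrix(0, B, scheme$n_chunks * scheme$chunk_len)
  for (b in seq_len(B))
    out[b, ] <- unchunk_spectrum(
      Tk[(b - 1) * scheme$n_chunks + seq_len(scheme$n_chunks), , drop = FALSE])
  out
}
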