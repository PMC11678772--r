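test_that("chunking is a contiguous, invertible partition", {
  sch <- chunk_scheme(46L, 1000L)
  x <- rnorm(46000)
  ch <- chunk_spectrum(x, sch)
  expect_equal(dim(ch), c(46, 1000))
  expect_equal(ch[1, ], x[1:1000])          # order-preserving, contiguous
  expect_equal(ch[46, ], x[45001:46000])
  expect_identical(unchunk_spectrum(ch), x)
  expect_error(chunk_spectrum(rnorm(45999), sch), "requires length 46000")
})

test_that("every conversion network maps length-L inputs to length-L outputs", {
  specs <- tiny_specs()
  X <- list()
  for (nm in setdiff(names(specs), "quant_mlp")) {
    spec <- specs[[nm]]
    net <- build_network(spec)
    out <- predict(net, matrix(rnorm(3 * spec$input_len), 3))
    expect_equal(dim(out), c(3, spec$input_len), label = nm)
    expect_true(all(is.finite(out)), label = nm)
  }
  q <- build_network(specs$quant_mlp)
  expect_equal(dim(predict(q, matrix(rnorm(2 * 60), 2))), c(2, 3))
  expect_error(predict(q, matrix(0, 1, 59)), "dimension mismatch")
})

test_that("built parameter counts match the closed-form counts", {
  for (spec in tiny_specs())
    expect_equal(n_params(build_network(spec)), param_count(spec),
                 label = spec$architecture)

  # full-scale counts from the layer-wise counting oracle
  dae_full <- model_spec("dae")
  widths <- c(46000, 2000, 200, 2000, 46000)
  oracle <- sum(widths[-5] * widths[-1]) + sum(widths[-1])
  expect_equal(param_count(dae_full), oracle)
  expect_equal(param_count(dae_full), 184850200)

  mlp <- model_spec("quant_mlp", n_outputs = 21L)
  expect_equal(param_count(mlp), 46000 * 200 + 200 * 21 + 200 + 21)
})

test_that("identical (spec, seed) build identical networks", {
  for (nm in c("dae", "transformer", "tcn")) {
    s <- tiny_specs(seed = 42L)[[nm]]
    expect_identical(build_network(s)$params, build_network(s)$params)
    s2 <- tiny_specs(seed = 43L)[[nm]]
    expect_false(identical(build_network(s)$params, build_network(s2)$params))
  }
})

test_that("specs validate their fields", {
  expect_error(model_spec("dae", widths = c(-10L, 5L)), "widths")
  expect_error(model_spec("transformer", input_len = 24L,
                          scheme = chunk_scheme(4L, 6L),
                          d_model = 10L, n_heads = 4L),
               "not divisible")
  expect_error(model_spec("quant_mlp", n_outputs = 0L), "n_outputs")
  expect_error(model_spec("transformer", input_len = 100L,
                          scheme = chunk_scheme(4L, 6L)),
               "incompatible")
  expect_error(model_spec("tcn", dropout = 1.2), "dropout")
})

test_that("the transformer is equivariant to chunk permutations without dropout", {
  spec <- model_spec("transformer", 24L, 3L, scheme = chunk_scheme(4L, 6L),
                     d_model = 8L, n_layers = 2L, n_heads = 2L, d_ff = 16L,
                     dropout = 0.1)   # dropout off in inference mode
  net <- build_network(spec)
  x <- rnorm(24)
  perm <- c(3, 1, 4, 2)
  permute <- function(v) unchunk_spectrum(chunk_spectrum(v, spec$scheme)[perm, ])
  y <- drop(predict(net, matrix(x, 1)))
  y_perm <- drop(predict(net, matrix(permute(x), 1)))
  expect_equal(y_perm, permute(y), tolerance = 1e-10)
})

test_that("the chunked U-Net equals per-chunk application of the U-Net", {
  sch <- chunk_scheme(3L, 10L)
  s_chunked <- model_spec("unet_chunks", 30L, 9L,
                          channels = c(2L, 3L, 4L, 5L), scheme = sch)
  s_plain <- model_spec("unet", 10L, 9L, channels = c(2L, 3L, 4L, 5L))
  chunked <- build_network(s_chunked)
  plain <- build_network(s_plain)
  plain$params <- chunked$params    # same seed layout, share weights
  x <- rnorm(30)
  per_chunk <- as.vector(t(predict(plain, chunk_spectrum(x, sch))))
  expect_equal(drop(predict(chunked, matrix(x, 1))), per_chunk,
               tolerance = 1e-12)
})

test_that("the U-Net differs from the CAE by exactly one 32-channel skip", {
  s_cae <- model_spec("cae")
  s_unet <- model_spec("unet")
  g_cae <- fieldlift:::cae_channels(s_cae, skip = FALSE)
  g_unet <- fieldlift:::cae_channels(s_unet, skip = TRUE)
  d <- g_unet$ins - g_cae$ins
  expect_equal(sum(d != 0), 1)
  expect_equal(d[d != 0], 32)                      # encoder 32-ch activation
  expect_equal(g_unet$outs[which(d != 0)], 32)     # onto the decoder 32 layer
  expect_equal(g_cae$outs, c(16, 32, 64, 128, 64, 32, 16, 1))
})

test_that("the TCN is causal with the receptive field of its dilations", {
  # receptive field = 1 + (k-1) * sum(2 * dilations) = 15 for kernel 2,
  # dilations (1, 2, 4), two convolutions per block
  spec <- model_spec("tcn", 64L, 2L, channels = c(3L, 4L, 5L), dropout = 0)
  net <- build_network(spec)
  # all-positive weights so no path is silenced by a ReLU at exactly zero
  net$params <- lapply(net$params, abs)
  base <- drop(predict(net, matrix(0, 1, 64)))
  probe <- function(pos) {
    x <- numeric(64); x[pos] <- 1
    which(abs(drop(predict(net, matrix(x, 1))) - base) > 1e-12)
  }
  touched <- probe(30)
  expect_gte(min(touched), 30)        # causal: nothing before the impulse
  expect_lte(max(touched), 30 + 14)   # receptive field spans 15 samples
  expect_equal(max(probe(1)), 15)
})
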