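# Small shared fixtures, built in code.

tiny_axis <- function(n = 200L, freq = 400) make_axis(n, -0.32, 10.2, freq)

# a three-metabolite library with known, hand-chosen multiplets
toy_library <- function(lw = 1.0) list(
  spin_model("ala", list(multiplet(1.47, c(7.2, 7.2), 3, lw),   # 1:2:1
                         multiplet(3.78, 7.2, 1, lw))),
  spin_model("lac", list(multiplet(1.33, 7.0, 3, lw),
                         multiplet(4.11, 7.0, 1, lw))),
  spin_model("tsp_like", multiplet(8.45, numeric(0), 2, lw)))

toy_aug <- function(...) augmentation_config(...)

# tiny architecture specs used across model/training tests
tiny_specs <- function(seed = 1L) list(
  dae = model_spec("dae", 60L, seed, widths = c(16L, 6L)),
  cae = model_spec("cae", 30L, seed, channels = c(2L, 3L, 4L, 5L)),
  unet = model_spec("unet", 30L, seed, channels = c(2L, 3L, 4L, 5L)),
  unet_chunks = model_spec("unet_chunks", 30L, seed,
                           channels = c(2L, 3L, 4L, 5L),
                           scheme = chunk_scheme(3L, 10L)),
  tcn = model_spec("tcn", 30L, seed, channels = c(3L, 4L, 5L)),
  transformer = model_spec("transformer", 24L, seed,
                           scheme = chunk_scheme(4L, 6L), d_model = 8L,
                           n_layers = 2L, n_heads = 2L, d_ff = 16L),
  quant_mlp = model_spec("quant_mlp", 60L, seed, hidden = 7L,
                         n_outputs = 3L))
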