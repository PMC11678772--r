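test_that("composition draws follow the concentration and dropout rules", {
  lib <- toy_library()
  aug <- augmentation_config()
  withr::with_seed(2, {
    full <- replicate(500, draw_composition(lib, aug, use_dropout = FALSE))
    expect_true(all(full >= 1 & full <= 50))
    drop <- replicate(500, draw_composition(lib, aug, use_dropout = TRUE))
    expect_true(all(drop[drop > 0] >= 1))
    freq <- mean(drop > 0)
    expect_gt(freq, 0.4); expect_lt(freq, 0.6)
  })
  expect_length(draw_composition(list(), aug), 0)
})

test_that("paired samples share one composition and differ only as fields do", {
  lib <- toy_library(lw = 2.0)
  gen <- prepare_generator(lib, augmentation_config(ref_linewidth_hz = 2),
                           tiny_axis(4600L))
  s <- with_seed(31, generate_paired_sample(gen, use_dropout = TRUE))
  expect_identical(s$lf$composition, s$hf$composition)
  expect_equal(length(s$conc), 3)
  expect_identical(s$lf$provenance$artifacts, s$hf$provenance$artifacts)
  expect_identical(s$lf$provenance$baseline_offset,
                   s$hf$provenance$baseline_offset)
  # both rendered on the standard grid length
  expect_equal(s$lf$axis$n_points, s$hf$axis$n_points)
  expect_equal(s$lf$axis$spectrometer_freq, 100)
  expect_equal(s$hf$axis$spectrometer_freq, 400)
})

test_that("a doublet's peak separation is 4x wider at 100 MHz than 400 MHz", {
  lib <- list(spin_model("dbl", multiplet(4.0, 8.0, 2, 1)))
  aug <- augmentation_config(noise_pp_frac = 0, shift_max_ppb = 0,
                             baseline_max_frac = 0, max_singlets = 0,
                             max_triplets = 0)
  gen <- prepare_generator(lib, aug, make_axis(46000L, -0.32, 10.2, 400))
  s <- with_seed(1, generate_paired_sample(gen))
  sep <- function(sp) {
    y <- sp$intensities
    g <- ppm_values(sp$axis)
    win <- g > 3.5 & g < 4.5
    pk <- which(diff(sign(diff(y * win))) == -2) + 1
    diff(range(g[pk]))
  }
  expect_equal(sep(s$lf), 4 * sep(s$hf), tolerance = 0.02)
})

test_that("the low-field noise multiplier scales the noise band", {
  lib <- toy_library()
  base_aug <- augmentation_config(shift_max_ppb = 0, baseline_max_frac = 0,
                                  max_singlets = 0, max_triplets = 0)
  adj_aug <- augmentation_config(lf_noise_multiplier = 4, shift_max_ppb = 0,
                                 baseline_max_frac = 0, max_singlets = 0,
                                 max_triplets = 0)
  ax <- tiny_axis(20000L)
  g1 <- prepare_generator(lib, base_aug, ax)
  g4 <- prepare_generator(lib, adj_aug, ax)
  g0 <- prepare_generator(lib, augmentation_config(
    noise_pp_frac = 0, shift_max_ppb = 0, baseline_max_frac = 0,
    max_singlets = 0, max_triplets = 0), ax)
  s1 <- with_seed(9, generate_paired_sample(g1))
  s4 <- with_seed(9, generate_paired_sample(g4))
  s0 <- with_seed(9, generate_paired_sample(g0))   # noiseless twin
  expect_equal(s4$lf$provenance$noise_pp, 4 * s1$lf$provenance$noise_pp)
  expect_equal(s4$hf$provenance$noise_pp, s1$hf$provenance$noise_pp)
  # same seed, same underlying uniforms: the realized low-field noise is
  # exactly four times larger, the high-field noise identical
  expect_equal(s4$lf$intensities - s0$lf$intensities,
               4 * (s1$lf$intensities - s0$lf$intensities))
  expect_equal(s4$hf$intensities, s1$hf$intensities)
})

test_that("corpus counts, split ratio, and determinism hold at toy scale", {
  lib <- toy_library()
  aug <- augmentation_config()
  cfg <- corpus_config(10L, 10L, 16L, 4L, n_test = 3L, seed = 77L)
  ax <- tiny_axis(400L)
  corp <- build_corpus(lib, aug, cfg, ax)
  expect_equal(nrow(corp$train$lf), 16L)
  expect_equal(nrow(corp$val$lf), 4L)
  expect_equal(nrow(corp$test$lf), 3L)
  expect_equal(ncol(corp$train$conc), 3L)
  # dropout half: zeros occur; all-present half: none
  expect_true(any(corp$train$conc == 0) || any(corp$val$conc == 0))
  # test split is all-present
  expect_true(all(corp$test$conc > 0))

  expect_error(corpus_config(10L, 10L, 15L, 4L), "inconsistent counts")

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus(corp, d1)
  write_corpus(build_corpus(lib, aug, cfg, ax), d2)
  for (f in list.files(d1)) {
    if (f == "manifest.json") next
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  back <- read_corpus(d1)
  expect_equal(back$train$lf, corp$train$lf)
  expect_equal(back$library_names, corp$library_names)
})

test_that("fixed-concentration test samples are constant, linear, validated", {
  lib <- toy_library(2)
  gen <- prepare_generator(lib, augmentation_config(ref_linewidth_hz = 2),
                           tiny_axis(2000L))
  smp <- build_fixed_concentration_tests(gen, c(5, 25, 50), noise = FALSE)
  expect_length(smp, 3)
  for (s in smp) expect_length(unique(s$conc), 1)
  # linearity of the metabolite part (reference is fixed at 2.96 mM)
  ref <- gen$ref_hf
  expect_equal(smp[[2]]$hf$intensities - ref,
               5 * (smp[[1]]$hf$intensities - ref), tolerance = 1e-10)
  expect_warning(build_fixed_concentration_tests(gen, 60, noise = FALSE),
                 "outside")
  expect_error(build_fixed_concentration_tests(gen, numeric(0)), "non-empty")
})

test_that("integrating an isolated metabolite recovers its concentration", {
  # label-consistency oracle: integral / (protons * pi * GAMMA_REF) == conc
  lib <- list(spin_model("iso", multiplet(5.0, c(7, 7), 3, 1)))
  ax <- make_axis(20000L, -0.32, 10.2, 400)
  aug <- augmentation_config(noise_pp_frac = 0, shift_max_ppb = 0,
                             baseline_max_frac = 0, max_singlets = 0,
                             max_triplets = 0)
  gen <- prepare_generator(lib, aug, ax)
  s <- with_seed(4, generate_paired_sample(gen))
  g <- ppm_values(ax)
  win <- g > 3.5 & g < 6.5       # isolated region around the multiplet
  integral <- pracma::trapz(g[win], s$hf$intensities[win])
  conc_hat <- integral / (3 * pi * (0.5 / 400))
  expect_equal(conc_hat, unname(s$conc["iso"]), tolerance = 0.02)
})
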