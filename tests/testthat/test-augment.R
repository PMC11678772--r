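make_base <- function(n = 2000L) {
  ax <- make_axis(n, -0.32, 10.2, 400)
  spectrum_record(ax, numeric(n))
}

test_that("the reference singlet lands at 0 ppm with the configured height", {
  aug <- augmentation_config()
  sp <- add_reference(make_base(46000L), aug)
  expect_equal(unname(sp$composition["TSP"]), 2.96)
  expect_equal(which.max(sp$intensities),
               which.min(abs(ppm_values(sp$axis))))
  # amplitude convention: 9 protons at 2.96 mM, 1 Hz linewidth at 400 MHz
  expect_equal(sp$provenance$ref_height, 9 * 2.96, tolerance = 0.01)
  expect_error(add_reference(sp, aug), "reference already present")
})

test_that("uniform noise respects the peak-to-peak bound and scales with the multiplier", {
  aug <- augmentation_config()
  base <- add_reference(make_base(100000L), aug)
  h <- base$provenance$ref_height
  withr::with_seed(1, {
    noisy <- add_noise(base, aug, multiplier = 1)
    added <- noisy$intensities - base$intensities
    expect_lte(max(added) - min(added), 0.001 * h)
    expect_gt(max(added) - min(added), 0.0009 * h)  # actually fills the band

    n4 <- add_noise(base, aug, multiplier = 4)
    ratio <- sd(n4$intensities - base$intensities) / sd(added)
    expect_equal(ratio, 4, tolerance = 0.05)
  })
  quiet <- add_noise(base, augmentation_config(noise_pp_frac = 0))
  expect_identical(quiet$intensities, base$intensities)
  expect_error(add_noise(base, aug, multiplier = 0), "multiplier")
  expect_error(add_noise(make_base(), aug), "reference")
})

test_that("jitter is a bounded integer-grid translation", {
  ax <- make_axis(46000L, -0.32, 10.2, 400)
  lib <- toy_library()
  comp <- render_metabolite(lib[[1]], ax, 10)
  aug <- augmentation_config()
  withr::with_seed(7, for (i in 1:25) {
    j <- jitter_metabolite(comp, aug)
    expect_lte(abs(j$provenance$jitter_ppb), 3.4)
    expect_equal(as.integer(j$provenance$jitter_points),
                 as.integer(round(j$provenance$jitter_ppb * 1e-3 / ax$dppm)))
  })
  frozen <- jitter_metabolite(comp, augmentation_config(shift_max_ppb = 0))
  expect_identical(frozen$intensities, comp$intensities)
  # translation conserves the sum exactly when nothing crosses the edge
  y <- c(0, 0, 0, 1, 5, 2, 0, 0, 0, 0)
  for (s in -3:3)
    expect_identical(sum(fieldlift:::shift_intensities(y, s)), sum(y))
})

test_that("baseline shifts are bounded constants", {
  aug <- augmentation_config()
  base <- add_reference(make_base(), aug)
  h <- base$provenance$ref_height
  withr::with_seed(3, for (i in 1:25) {
    b <- shift_baseline(base, aug)
    off <- b$provenance$baseline_offset
    expect_lte(abs(off), 0.006 * h)
    expect_equal(b$intensities - base$intensities, rep(off, length(b$intensities)))
    expect_equal(mean(b$intensities) - mean(base$intensities), off)
  })
  same <- shift_baseline(base, augmentation_config(baseline_max_frac = 0))
  expect_identical(same$intensities, base$intensities)
})

test_that("artifact counts, types and determinism follow the configuration", {
  aug <- augmentation_config()
  base <- make_base(1000L)
  withr::with_seed(11, {
    counts <- t(replicate(300, {
      a <- add_artifacts(base, aug)$provenance$artifacts
      c(singlets = sum(a$type == "singlet"), triplets = sum(a$type == "triplet"))
    }))
  })
  expect_true(all(counts >= 0 & counts <= 3))
  expect_setequal(unique(counts[, "singlets"]), 0:3)

  no_trip <- augmentation_config(include_triplets = FALSE)
  withr::with_seed(12, {
    trips <- replicate(100, sum(add_artifacts(base, no_trip)$
                                  provenance$artifacts$type == "triplet"))
  })
  expect_true(all(trips == 0))

  a1 <- withr::with_seed(5, add_artifacts(base, aug))
  a2 <- withr::with_seed(5, add_artifacts(base, aug))
  expect_identical(a1$intensities, a2$intensities)

  # amplitudes are concentration-equivalent draws within [conc_lo, conc_hi]
  amps <- unlist(withr::with_seed(6, replicate(50, simplify = FALSE,
    add_artifacts(base, aug)$provenance$artifacts$amp)))
  expect_true(all(amps >= 1 & amps <= 50))
})

test_that("artifact triplets carry the generic 1:2:1 field-scaled pattern", {
  art <- data.frame(type = "triplet", center_ppm = 5.0, amp = 10)
  aug <- augmentation_config()
  ax400 <- make_axis(40001L, 4, 6, 400)
  ax100 <- make_axis(40001L, 4, 6, 100)
  y400 <- fieldlift:::render_artifacts(art, ax400, aug)
  y100 <- fieldlift:::render_artifacts(art, ax100, aug)
  sep <- function(y, ax) {
    pk <- which(diff(sign(diff(y))) == -2) + 1
    diff(range(ppm_values(ax)[pk]))
  }
  # outer-line separation = 2 * J / freq, four times wider at 100 MHz
  expect_equal(sep(y400, ax400), 2 * 7 / 400, tolerance = 1e-3)
  expect_equal(sep(y100, ax100), 4 * sep(y400, ax400), tolerance = 1e-3)
})
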