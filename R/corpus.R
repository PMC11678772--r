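# Corpus construction: paired LF/HF mixtures with shared composition,
# jitter, artifact and baseline draws, independent per-field noise.

#' Corpus configuration
#'
#' Counts and seeds for a paired-spectrum corpus.  Defaults reproduce the
#' full-scale conditions: 10,000 mixtures with every metabolite present plus
#' 10,000 with 50% metabolite dropout, split 16,000:4,000 into training and
#' validation, rendered at 100 and 400 MHz.  `n_test` controls the number of
#' held-out all-metabolites-present test pairs generated alongside the corpus
#' (the evaluation default is 100).
#'
#' @param n_all_present,n_with_dropout mixture counts for the two halves.
#' @param train_count,val_count split sizes; must sum to the total.
#' @param n_test held-out test pairs.
#' @param seed integer seed fully determining the corpus.
#' @param lf_mhz,hf_mhz the two spectrometer frequencies.
#' @export
corpus_config <- function(n_all_present = 10000L, n_with_dropout = 10000L,
                          train_count = 16000L, val_count = 4000L,
                          n_test = 100L, seed = 1L,
                          lf_mhz = 100, hf_mhz = 400) {
  cfg <- list(n_all_present = as.integer(n_all_present),
              n_with_dropout = as.integer(n_with_dropout),
              train_count = as.integer(train_count),
              val_count = as.integer(val_count),
              n_test = as.integer(n_test),
              seed = as.integer(seed),
              lf_mhz = lf_mhz, hf_mhz = hf_mhz)
  if (cfg$train_count + cfg$val_count != cfg$n_all_present + cfg$n_with_dropout)
    stopf("inconsistent counts: train_count + val_count (%d) must equal n_all_present + n_with_dropout (%d)",
          cfg$train_count + cfg$val_count,
          cfg$n_all_present + cfg$n_with_dropout)
  structure(cfg, class = "corpus_config")
}

#' Draw a mixture composition
#'
#' Each included metabolite receives a concentration uniform in
#' `[conc_lo, conc_hi]`; with `use_dropout`, each metabolite is independently
#' left out (concentration 0) with probability `dropout_prob`.
#'
#' @param library list of [spin_model()] objects.
#' @param cfg an [augmentation_config()].
#' @param use_dropout logical.
#' @return named concentration vector in library order (0 = dropped out).
#' @export
draw_composition <- function(library, cfg = augmentation_config(),
                             use_dropout = FALSE) {
  k <- length(library)
  if (!k) return(stats::setNames(numeric(0), character(0)))
  conc <- stats::runif(k, cfg$conc_lo, cfg$conc_hi)
  if (use_dropout)
    conc[stats::runif(k) < cfg$dropout_prob] <- 0
  stats::setNames(conc, vapply(library, `[[`, "", "name"))
}

#' Prepare a paired-sample generator
#'
#' Pre-renders every library metabolite at unit concentration on the low- and
#' high-field axes (superposition makes mixtures linear combinations of these
#' unit spectra) and pre-renders the reference singlet at both fields.  The
#' returned generator is consumed by [generate_paired_sample()] and
#' [build_corpus()].
#'
#' @param library list of [spin_model()] objects.
#' @param aug an [augmentation_config()].
#' @param axis template [make_axis()] giving grid size and ppm bounds (its
#'   frequency is ignored; `lf_mhz`/`hf_mhz` are used).
#' @param lf_mhz,hf_mhz the two spectrometer frequencies.
#' @export
prepare_generator <- function(library, aug = augmentation_config(),
                              axis = default_axis(), lf_mhz = 100,
                              hf_mhz = 400) {
  lf_axis <- make_axis(axis$n_points, axis$ppm_min, axis$ppm_max, lf_mhz)
  hf_axis <- make_axis(axis$n_points, axis$ppm_min, axis$ppm_max, hf_mhz)
  ref <- reference_model(aug)
  ref_lf <- render_metabolite(ref, lf_axis, aug$ref_conc)$intensities
  ref_hf <- render_metabolite(ref, hf_axis, aug$ref_conc)$intensities
  structure(list(
    library = library,
    names = vapply(library, `[[`, "", "name"),
    aug = aug, lf_axis = lf_axis, hf_axis = hf_axis,
    unit_lf = render_library(library, lf_axis),
    unit_hf = render_library(library, hf_axis),
    ref_lf = ref_lf, ref_hf = ref_hf,
    ref_height = max(ref_hf)),   # common noise/baseline normalizer
    class = "pair_generator")
}

#' Generate one paired low-field/high-field sample
#'
#' One composition, one set of per-metabolite jitters (in ppb), one artifact
#' set and one baseline offset are drawn once and rendered at both fields, so
#' the pair differs only in spectral resolution and in its independent noise
#' draws; the low-field noise amplitude is scaled by `lf_noise_multiplier`.
#' Noise and baseline fractions are normalized against the high-field
#' reference peak height, the pair's common intensity scale.
#'
#' Draws come from R's RNG; seed with [with_seed()] or `set.seed()` for
#' reproducibility.
#'
#' @param gen a [prepare_generator()] object.
#' @param use_dropout logical, passed to [draw_composition()].
#' @return a `paired_sample`: `lf` and `hf` [spectrum_record()]s plus `conc`,
#'   the concentration vector in library order.
#' @export
generate_paired_sample <- function(gen, use_dropout = FALSE) {
  stopifnot(inherits(gen, "pair_generator"))
  aug <- gen$aug
  conc <- draw_composition(gen$library, aug, use_dropout)
  jit <- sample(c(-1, 1), length(conc), replace = TRUE) *
    stats::runif(length(conc), 0, aug$shift_max_ppb)
  art <- draw_artifacts(aug, gen$lf_axis$ppm_min, gen$lf_axis$ppm_max)
  base_off <- sample(c(-1, 1), 1) *
    stats::runif(1, 0, aug$baseline_max_frac * gen$ref_height)
  noise_a <- aug$noise_pp_frac * gen$ref_height

  render_field <- function(unit, ref_y, axis, mult) {
    shifts <- round((jit * 1e-3) / axis$dppm)
    y <- numeric(axis$n_points)
    for (k in seq_along(conc)) if (conc[k] > 0)
      y <- y + conc[k] * shift_intensities(unit[k, ], shifts[k])
    y <- y + ref_y + render_artifacts(art, axis, aug) + base_off
    a <- mult * noise_a
    if (a > 0) y <- y + stats::runif(axis$n_points, -a / 2, a / 2)
    spectrum_record(axis, y,
                    c(conc[conc > 0], stats::setNames(aug$ref_conc, REFERENCE_NAME)),
                    provenance = list(field_mhz = axis$spectrometer_freq,
                                      ref_height = max(ref_y),
                                      noise_pp = a, baseline_offset = base_off,
                                      jitter_ppb = jit, artifacts = art))
  }
  lf <- render_field(gen$unit_lf, gen$ref_lf, gen$lf_axis,
                     aug$lf_noise_multiplier)
  hf <- render_field(gen$unit_hf, gen$ref_hf, gen$hf_axis, 1)
  structure(list(lf = lf, hf = hf, conc = conc), class = "paired_sample")
}

#' Build a paired training corpus
#'
#' Generates `n_all_present` mixtures with every metabolite present and
#' `n_with_dropout` mixtures with 50% metabolite dropout, splits them
#' train/validation by a seeded shuffle, and generates `n_test` held-out
#' all-present test pairs.  `(library, aug, cfg)` fully determine the output:
#' two calls with equal seeds are identical.
#'
#' @param library list of [spin_model()] objects.
#' @param aug an [augmentation_config()].
#' @param cfg a [corpus_config()].
#' @param axis template axis (grid size and ppm bounds).
#' @return a `spectra_corpus`: `train`, `val`, `test` splits, each a list of
#'   matrices `lf`, `hf` (samples x points) and `conc` (samples x
#'   metabolites); plus the generator configs and a manifest.
#' @export
build_corpus <- function(library, aug = augmentation_config(),
                         cfg = corpus_config(), axis = default_axis()) {
  stopifnot(inherits(cfg, "corpus_config"))
  gen <- prepare_generator(library, aug, axis, cfg$lf_mhz, cfg$hf_mhz)
  n <- cfg$n_all_present + cfg$n_with_dropout
  p <- axis$n_points; k <- length(library)
  lf <- matrix(0, n, p); hf <- matrix(0, n, p); conc <- matrix(0, n, k)
  colnames(conc) <- gen$names
  with_seed(derive_seed(cfg$seed, "samples"), {
    for (i in seq_len(n)) {
      s <- generate_paired_sample(gen, use_dropout = i > cfg$n_all_present)
      lf[i, ] <- s$lf$intensities
      hf[i, ] <- s$hf$intensities
      conc[i, ] <- s$conc
    }
  })
  idx <- with_seed(derive_seed(cfg$seed, "split"), sample.int(n))
  tr <- idx[seq_len(cfg$train_count)]
  va <- idx[cfg$train_count + seq_len(cfg$val_count)]
  test <- with_seed(derive_seed(cfg$seed, "test"), {
    ts <- lapply(seq_len(cfg$n_test), function(i)
      generate_paired_sample(gen, use_dropout = FALSE))
    list(lf = do.call(rbind, lapply(ts, function(s) s$lf$intensities)),
         hf = do.call(rbind, lapply(ts, function(s) s$hf$intensities)),
         conc = do.call(rbind, lapply(ts, function(s) s$conc)))
  })
  structure(list(
    train = list(lf = lf[tr, , drop = FALSE], hf = hf[tr, , drop = FALSE],
                 conc = conc[tr, , drop = FALSE]),
    val = list(lf = lf[va, , drop = FALSE], hf = hf[va, , drop = FALSE],
               conc = conc[va, , drop = FALSE]),
    test = test,
    library_names = gen$names,
    lf_axis = gen$lf_axis, hf_axis = gen$hf_axis,
    aug = aug, config = cfg,
    manifest = list(package_version = as.character(utils::packageVersion("fieldlift")),
                    seed = cfg$seed,
                    library_hash = object_md5(library),
                    n_metabolites = k, n_points = p)),
    class = "spectra_corpus")
}

#' @export
print.spectra_corpus <- function(x, ...) {
  cat(sprintf("<spectra_corpus> %d train / %d val / %d test pairs, %d points, %d metabolites\n",
              nrow(x$train$lf), nrow(x$val$lf), nrow(x$test$lf),
              ncol(x$train$lf), length(x$library_names)))
  invisible(x)
}

#' Fixed-concentration quantification test spectra
#'
#' One paired sample per level with every library metabolite at that level:
#' no dropout, no jitter, no baseline shift, and no artifacts beyond the
#' reference singlet.  A single standard-amplitude noise draw is added unless
#' `noise = FALSE`.
#'
#' @param gen a [prepare_generator()] object.
#' @param levels non-empty vector of concentration levels (mM); the standard
#'   evaluation uses 5, 25 and 50 mM.
#' @param noise logical; add one standard noise draw per field.
#' @return list of `paired_sample` objects.
#' @export
build_fixed_concentration_tests <- function(gen, levels = c(5, 25, 50),
                                            noise = TRUE) {
  stopifnot(inherits(gen, "pair_generator"))
  if (!length(levels)) stopf("'levels' must be non-empty")
  aug <- gen$aug
  out_of_range <- levels < 0 | levels > aug$conc_hi
  if (any(out_of_range))
    warning(sprintf("level(s) %s outside [0, %g] mM",
                    paste(levels[out_of_range], collapse = ", "), aug$conc_hi))
  lapply(levels, function(lv) {
    conc <- stats::setNames(rep(lv, length(gen$library)), gen$names)
    make_field <- function(unit, ref_y, axis, mult) {
      y <- drop(conc %*% unit) + ref_y
      a <- if (noise) mult * aug$noise_pp_frac * gen$ref_height else 0
      if (a > 0) y <- y + stats::runif(axis$n_points, -a / 2, a / 2)
      spectrum_record(axis, y,
                      c(conc, stats::setNames(aug$ref_conc, REFERENCE_NAME)),
                      provenance = list(field_mhz = axis$spectrometer_freq,
                                        level_mM = lv, noise_pp = a))
    }
    structure(list(
      lf = make_field(gen$unit_lf, gen$ref_lf, gen$lf_axis,
                      aug$lf_noise_multiplier),
      hf = make_field(gen$unit_hf, gen$ref_hf, gen$hf_axis, 1),
      conc = conc), class = "paired_sample")
  })
}

#' Persist and reload a corpus
#'
#' The on-disk container is a directory holding one serialized matrix per
#' split/field (`train_lf.rds`, ..., `test_conc.rds`), the axes and configs,
#' and a JSON manifest recording seed, library hash, package version and the
#' md5 of every matrix file.  Writing is deterministic: equal
#' `(library, aug, config)` produce byte-identical directories.
#'
#' @param corpus a `spectra_corpus`.
#' @param dir output directory (created if needed).
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "spectra_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (split in c("train", "val", "test"))
    for (part in c("lf", "hf", "conc")) {
      f <- file.path(dir, sprintf("%s_%s.rds", split, part))
      saveRDS(corpus[[split]][[part]], f, version = 2)
      files[sprintf("%s_%s", split, part)] <- unname(tools::md5sum(f))
    }
  saveRDS(corpus[c("library_names", "lf_axis", "hf_axis", "aug", "config")],
          file.path(dir, "meta.rds"), version = 2)
  manifest <- c(corpus$manifest, list(files = as.list(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  meta <- readRDS(file.path(dir, "meta.rds"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list()
  for (split in c("train", "val", "test")) {
    out[[split]] <- list()
    for (part in c("lf", "hf", "conc"))
      out[[split]][[part]] <- readRDS(file.path(dir, sprintf("%s_%s.rds",
                                                             split, part)))
  }
  structure(c(out, meta, list(manifest = manifest)), class = "spectra_corpus")
}
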