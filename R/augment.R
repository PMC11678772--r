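# Augmentation workflow: reference singlet, uniform noise, per-metabolite
# chemical-shift jitter, baseline offset, artifact singlets/triplets.

ARTIFACT_TRIPLET_J <- 7.0  # Hz, generic 1:2:1 triplet template

#' Augmentation configuration
#'
#' Collects every nuisance parameter of the mixture-generation workflow.
#' Defaults are the standard corpus conditions: uniform noise with
#' peak-to-peak amplitude 0.1% of the quantitative reference peak height,
#' chemical-shift jitter up to 3.4 ppb, baseline offsets up to 0.6% of the
#' reference height, up to three artifact singlets and three artifact
#' triplets per spectrum, 50% metabolite dropout (when enabled), mixture
#' concentrations uniform in 1-50 mM, and a 2.96 mM reference singlet.
#'
#' @param noise_pp_frac peak-to-peak noise amplitude as a fraction of the
#'   reference peak height.
#' @param lf_noise_multiplier multiplier (>= 1) applied to the low-field noise
#'   amplitude; 4 gives the adjusted-SNR corpora.
#' @param shift_max_ppb maximum chemical-shift jitter, parts per billion.
#' @param baseline_max_frac maximum baseline offset as a fraction of the
#'   reference peak height.
#' @param max_singlets,max_triplets maximum artifact counts per spectrum.
#' @param include_triplets logical; quantification corpora set this `FALSE`.
#' @param dropout_prob probability a metabolite is left out of a mixture in
#'   the dropout half of a corpus.
#' @param conc_lo,conc_hi mixture concentration bounds (mM).
#' @param ref_conc reference singlet concentration (mM).
#' @param ref_linewidth_hz linewidth given to the reference and artifact
#'   lines (Hz).
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(noise_pp_frac = 0.001,
                                lf_noise_multiplier = 1,
                                shift_max_ppb = 3.4,
                                baseline_max_frac = 0.006,
                                max_singlets = 3L,
                                max_triplets = 3L,
                                include_triplets = TRUE,
                                dropout_prob = 0.5,
                                conc_lo = 1, conc_hi = 50,
                                ref_conc = 2.96,
                                ref_linewidth_hz = 1.0) {
  if (noise_pp_frac < 0) stopf("invalid 'noise_pp_frac': must be >= 0")
  if (lf_noise_multiplier < 1) stopf("invalid 'lf_noise_multiplier': must be >= 1")
  if (dropout_prob < 0 || dropout_prob > 1)
    stopf("invalid 'dropout_prob': must be in [0, 1]")
  if (conc_lo > conc_hi) stopf("invalid concentration range: conc_lo > conc_hi")
  if (max_singlets < 0 || max_triplets < 0)
    stopf("invalid artifact counts: must be >= 0")
  structure(list(noise_pp_frac = noise_pp_frac,
                 lf_noise_multiplier = lf_noise_multiplier,
                 shift_max_ppb = shift_max_ppb,
                 baseline_max_frac = baseline_max_frac,
                 max_singlets = as.integer(max_singlets),
                 max_triplets = as.integer(max_triplets),
                 include_triplets = isTRUE(include_triplets),
                 dropout_prob = dropout_prob,
                 conc_lo = conc_lo, conc_hi = conc_hi,
                 ref_conc = ref_conc,
                 ref_linewidth_hz = ref_linewidth_hz),
            class = "augmentation_config")
}

REFERENCE_NAME <- "TSP"

# Reference singlet as a spin model (9 equivalent protons at 0.0 ppm).
reference_model <- function(cfg)
  spin_model(REFERENCE_NAME,
             multiplet(0.0, numeric(0), 9, cfg$ref_linewidth_hz))

#' Add the quantitative reference singlet
#'
#' Adds a 9-proton singlet at 0.0 ppm at `cfg$ref_conc` mM (the TSP-d4
#' analogue).  The realized peak height of the rendered reference is stored in
#' the record's provenance as `ref_height` and becomes the normalizer for the
#' noise and baseline fractions.
#'
#' @param spec a [spectrum_record()] whose composition does not yet contain
#'   the reference.
#' @param cfg an [augmentation_config()].
#' @export
add_reference <- function(spec, cfg = augmentation_config()) {
  stopifnot(inherits(spec, "spectrum_record"))
  if (REFERENCE_NAME %in% names(spec$composition))
    stopf("reference already present in composition")
  ref <- render_metabolite(reference_model(cfg), spec$axis, cfg$ref_conc)
  spec$intensities <- spec$intensities + ref$intensities
  spec$composition <- c(spec$composition,
                        stats::setNames(cfg$ref_conc, REFERENCE_NAME))
  spec$provenance$ref_height <- max(ref$intensities)
  spec
}

ref_height_of <- function(spec) {
  h <- spec$provenance$ref_height
  if (is.null(h))
    stopf("reference height unknown; call add_reference() first")
  h
}

#' Add uniformly distributed noise
#'
#' Adds i.i.d. Uniform(-a/2, +a/2) noise with peak-to-peak amplitude
#' `a = multiplier * noise_pp_frac * reference peak height`.  The reference
#' must have been added first (its height is the normalizer).  `ref_height`
#' may be supplied explicitly to normalize against another spectrum's
#' reference (paired generation normalizes both fields against the high-field
#' reference so the low-field multiplier is meaningful in absolute terms).
#'
#' @param spec a [spectrum_record()] carrying a reference height.
#' @param cfg an [augmentation_config()].
#' @param multiplier positive noise-amplitude multiplier.
#' @param ref_height optional explicit normalizer.
#' @export
add_noise <- function(spec, cfg = augmentation_config(), multiplier = 1,
                      ref_height = NULL) {
  stopifnot(inherits(spec, "spectrum_record"))
  if (!is.numeric(multiplier) || multiplier <= 0)
    stopf("invalid 'multiplier': must be > 0")
  h <- ref_height %||% ref_height_of(spec)
  a <- multiplier * cfg$noise_pp_frac * h
  if (a > 0)
    spec$intensities <- spec$intensities +
      stats::runif(spec$axis$n_points, -a / 2, a / 2)
  spec$provenance$noise_pp <- a
  spec
}

# integer grid translation, zero-filling vacated points
shift_intensities <- function(y, s) {
  n <- length(y)
  if (s == 0) return(y)
  if (abs(s) >= n) return(numeric(n))
  if (s > 0) c(numeric(s), y[1:(n - s)]) else c(y[(1 - s):n], numeric(-s))
}

apply_ppb_shift <- function(spec, delta_ppb) {
  s <- round((delta_ppb * 1e-3) / spec$axis$dppm)
  spec$intensities <- shift_intensities(spec$intensities, s)
  spec$provenance$jitter_ppb <- delta_ppb
  spec$provenance$jitter_points <- s
  spec
}

#' Jitter a metabolite component spectrum
#'
#' Translates a single metabolite's rendered component left or right by a
#' chemical-shift offset drawn uniformly in magnitude from (0, shift_max_ppb]
#' with random sign, realized as a nearest-integer grid translation (vacated
#' edge points are zero-filled).  Applied per metabolite before mixing, which
#' emulates small pH/temperature shifts of one compound.
#'
#' @param component a single metabolite's [spectrum_record()].
#' @param cfg an [augmentation_config()].
#' @export
jitter_metabolite <- function(component, cfg = augmentation_config()) {
  stopifnot(inherits(component, "spectrum_record"))
  delta <- sample(c(-1, 1), 1) * stats::runif(1, 0, cfg$shift_max_ppb)
  apply_ppb_shift(component, delta)
}

#' Shift the baseline by a random constant offset
#'
#' Adds `b ~ +/- Uniform(0, baseline_max_frac * reference height)` to every
#' point.
#'
#' @inheritParams add_noise
#' @export
shift_baseline <- function(spec, cfg = augmentation_config(),
                           ref_height = NULL) {
  stopifnot(inherits(spec, "spectrum_record"))
  h <- ref_height %||% ref_height_of(spec)
  b <- sample(c(-1, 1), 1) * stats::runif(1, 0, cfg$baseline_max_frac * h)
  spec$intensities <- spec$intensities + b
  spec$provenance$baseline_offset <- b
  spec
}

# Draw an artifact set (types, centers, amplitude scalars) without rendering,
# so one draw can be rendered consistently at both fields.
draw_artifacts <- function(cfg, ppm_min, ppm_max) {
  k_s <- sample(0:cfg$max_singlets, 1)
  k_t <- if (cfg$include_triplets) sample(0:cfg$max_triplets, 1) else 0L
  k <- k_s + k_t
  if (k == 0)
    return(data.frame(type = character(0), center_ppm = numeric(0),
                      amp = numeric(0)))
  data.frame(type = rep(c("singlet", "triplet"), c(k_s, k_t)),
             center_ppm = stats::runif(k, ppm_min, ppm_max),
             amp = stats::runif(k, cfg$conc_lo, cfg$conc_hi))
}

render_artifacts <- function(artifacts, axis, cfg) {
  y <- numeric(axis$n_points)
  if (!nrow(artifacts)) return(y)
  for (i in seq_len(nrow(artifacts))) {
    j <- if (artifacts$type[i] == "triplet")
      rep(ARTIFACT_TRIPLET_J, 2) else numeric(0)
    m <- multiplet(artifacts$center_ppm[i], j, 1, cfg$ref_linewidth_hz)
    y <- y + render_metabolite(spin_model("artifact", m), axis,
                               artifacts$amp[i])$intensities
  }
  y
}

#' Add artifact singlets and triplets at random chemical shifts
#'
#' Draws 0 to `max_singlets` singlets and (when `include_triplets`) 0 to
#' `max_triplets` generic 1:2:1 triplets (J = 7 Hz, field-scaled through the
#' stick-pattern machinery), each centered uniformly in the axis range with a
#' concentration-equivalent amplitude scalar uniform in
#' `[conc_lo, conc_hi]`.
#'
#' @inheritParams add_noise
#' @export
add_artifacts <- function(spec, cfg = augmentation_config()) {
  stopifnot(inherits(spec, "spectrum_record"))
  art <- draw_artifacts(cfg, spec$axis$ppm_min, spec$axis$ppm_max)
  spec$intensities <- spec$intensities + render_artifacts(art, spec$axis, cfg)
  spec$provenance$artifacts <- art
  spec
}
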