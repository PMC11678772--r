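# Parametric spin-multiplet models and field-dependent Lorentzian rendering.
#
# Amplitude convention: a 1-proton singlet at 1 mM with a 1.0 Hz linewidth has
# unit peak height when rendered at 400 MHz; every other amplitude follows by
# linearity.  With gamma the half-width at half maximum in ppm
# (gamma = 0.5 * linewidth_hz / freq) a line of weight w at conc c contributes
#   c * w * GAMMA_REF * gamma / ((x - x0)^2 + gamma^2),
# which has peak height c * w * GAMMA_REF / gamma and ppm-integral
# c * w * pi * GAMMA_REF independent of field and linewidth -- the physical
# statement that the integral is concentration-proportional.
GAMMA_REF <- 0.5 * 1.0 / 400   # HWHM (ppm) of a 1 Hz line at 400 MHz

#' Spin multiplet and metabolite spin model constructors
#'
#' A `multiplet` is one chemically equivalent proton group: a center chemical
#' shift, a list of scalar couplings in Hz (empty for a singlet), a proton
#' count (relative integral), and a Lorentzian full width at half maximum in
#' Hz.  A `spin_model` is a named, non-empty collection of multiplets and is
#' the package's parametric stand-in for one reference metabolite spectrum.
#'
#' @param center_ppm chemical shift of the multiplet center (ppm).
#' @param j_hz numeric vector of scalar couplings (Hz), possibly empty.
#' @param protons positive relative integral (proton count).
#' @param linewidth_hz full width at half maximum in Hz (> 0).
#' @export
multiplet <- function(center_ppm, j_hz = numeric(0), protons = 1,
                      linewidth_hz = 1.0) {
  if (!is.numeric(protons) || protons <= 0)
    stopf("invalid 'protons': must be > 0")
  if (!is.numeric(linewidth_hz) || linewidth_hz <= 0)
    stopf("invalid 'linewidth_hz': must be > 0")
  if (length(j_hz) && any(j_hz < 0))
    stopf("invalid 'j_hz': couplings must be >= 0 Hz")
  structure(list(center_ppm = as.numeric(center_ppm),
                 j_hz = as.numeric(j_hz),
                 protons = as.numeric(protons),
                 linewidth_hz = as.numeric(linewidth_hz)),
            class = "multiplet")
}

#' @param name metabolite identifier, unique within a library.
#' @param multiplets non-empty list of [multiplet()] objects.
#' @rdname multiplet
#' @export
spin_model <- function(name, multiplets) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stopf("invalid 'name': must be a non-empty string")
  if (inherits(multiplets, "multiplet")) multiplets <- list(multiplets)
  if (!length(multiplets) || !all(vapply(multiplets, inherits, TRUE, "multiplet")))
    stopf("invalid 'multiplets': need a non-empty list of multiplet objects")
  structure(list(name = name, multiplets = multiplets), class = "spin_model")
}

#' First-order stick pattern of a multiplet at a given field
#'
#' Applies the weak-coupling splitting rule: each coupling J splits every line
#' into two lines displaced by +/- J/(2 freq) ppm at half weight.  Coincident
#' lines (e.g. from repeated equal couplings) are merged with summed weights,
#' which yields the familiar binomial patterns (triplet 1:2:1, quartet
#' 1:3:3:1, ...).  Weights are normalized to sum to the proton count.
#'
#' Because J is field-independent in Hz, the ppm spread of the pattern scales
#' inversely with the spectrometer frequency: the same doublet is 4x wider in
#' ppm at 100 MHz than at 400 MHz.
#'
#' @param m a [multiplet()].
#' @param freq spectrometer frequency (MHz, > 0).
#' @return data.frame with columns `ppm` (line position) and `weight`
#'   (relative integral; sums to `m$protons`).
#' @export
multiplet_line_positions <- function(m, freq) {
  stopifnot(inherits(m, "multiplet"))
  if (!is.numeric(freq) || length(freq) != 1 || freq <= 0)
    stopf("invalid 'freq': spectrometer frequency must be > 0 MHz")
  pos <- 0; w <- 1
  for (J in m$j_hz) {
    d <- J / (2 * freq)
    pos <- c(pos - d, pos + d)
    w <- c(w, w) / 2
  }
  o <- order(pos); pos <- pos[o]; w <- w[o]
  grp <- cumsum(c(TRUE, diff(pos) > 1e-9))
  ppm <- as.numeric(tapply(pos * w, grp, sum) / tapply(w, grp, sum))
  weight <- as.numeric(tapply(w, grp, sum))
  data.frame(ppm = m$center_ppm + ppm, weight = weight * m$protons)
}

#' Spectrum container
#'
#' Couples an intensity vector to its axis, the mixture composition that
#' produced it (metabolite name -> concentration in mM) and free-form
#' provenance metadata.
#'
#' @param axis a [make_axis()] object.
#' @param intensities numeric vector, `length == axis$n_points`, all finite.
#' @param composition named numeric vector of concentrations (mM); may be
#'   empty.
#' @param provenance list of metadata (field, seed, augmentation draws, ...).
#' @export
spectrum_record <- function(axis, intensities,
                            composition = numeric(0), provenance = list()) {
  stopifnot(inherits(axis, "spectral_axis"))
  if (length(intensities) != axis$n_points)
    stopf("length(intensities) == %d but axis has %d points",
          length(intensities), axis$n_points)
  if (!all(is.finite(intensities)))
    stopf("intensities contain non-finite values")
  structure(list(axis = axis, intensities = as.numeric(intensities),
                 composition = composition, provenance = provenance),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record> %d points @ %g MHz, %d components, max %.4g\n",
              x$axis$n_points, x$axis$spectrometer_freq,
              length(x$composition), max(x$intensities)))
  invisible(x)
}

# Evaluate the Lorentzian contribution of a set of stick lines on a grid.
# `heights` is conc * weight in the package amplitude convention.
render_lines <- function(ppm_grid, line_ppm, line_weight, conc, gamma) {
  y <- numeric(length(ppm_grid))
  for (i in seq_along(line_ppm)) {
    d <- ppm_grid - line_ppm[i]
    y <- y + conc * line_weight[i] * GAMMA_REF * gamma[i] / (d * d + gamma[i]^2)
  }
  y
}

#' Render one metabolite spin model onto an axis
#'
#' Sums a Lorentzian for every stick line of every multiplet, with FWHM
#' `linewidth_hz / freq` ppm and amplitude proportional to
#' `conc x line weight` (see the package amplitude convention).
#'
#' @param model a [spin_model()].
#' @param axis target [make_axis()]; its `spectrometer_freq` sets both the
#'   stick pattern and the ppm linewidth.
#' @param conc concentration in mM (>= 0).
#' @return a [spectrum_record()] whose composition is `c(name = conc)`.
#' @export
render_metabolite <- function(model, axis, conc) {
  stopifnot(inherits(model, "spin_model"), inherits(axis, "spectral_axis"))
  if (!is.numeric(conc) || length(conc) != 1 || conc < 0)
    stopf("invalid 'conc': concentration must be >= 0 mM")
  grid <- ppm_values(axis)
  y <- numeric(axis$n_points)
  freq <- axis$spectrometer_freq
  for (m in model$multiplets) {
    lines <- multiplet_line_positions(m, freq)
    gamma <- rep(0.5 * m$linewidth_hz / freq, nrow(lines))
    y <- y + render_lines(grid, lines$ppm, lines$weight, conc, gamma)
  }
  comp <- stats::setNames(conc, model$name)
  spectrum_record(axis, y, comp,
                  provenance = list(field_mhz = freq, rendered = model$name))
}

# Render every model in a library at 1 mM onto an axis: rows = metabolites.
# Mixtures are then linear combinations of these unit spectra (superposition),
# which makes corpus generation cheap.
render_library <- function(library, axis) {
  mat <- t(vapply(library, function(mod)
    render_metabolite(mod, axis, 1)$intensities, numeric(axis$n_points)))
  rownames(mat) <- vapply(library, `[[`, "", "name")
  mat
}
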