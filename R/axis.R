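#' Construct a uniform chemical-shift axis
#'
#' A spectral axis is a uniform ppm grid tied to a proton Larmor frequency.
#' Low-field and high-field renderings of the same mixture share one grid, so
#' equal-length intensity vectors can be fed to the conversion networks; only
#' the frequency differs between the two renderings.  Storage order is
#' ascending ppm; display code may reverse to the NMR convention (high ppm on
#' the left).
#'
#' @param n_points number of grid points (>= 2).
#' @param ppm_min,ppm_max chemical-shift bounds in ppm, `ppm_max > ppm_min`.
#' @param freq spectrometer (proton Larmor) frequency in MHz.
#' @return An object of class `spectral_axis` with fields `n_points`,
#'   `ppm_min`, `ppm_max`, `spectrometer_freq` and the derived grid spacing
#'   `dppm = (ppm_max - ppm_min) / (n_points - 1)`.
#' @examples
#' ax <- make_axis(46000, -0.32, 10.2, 400)
#' head(ppm_values(ax))
#' @export
make_axis <- function(n_points, ppm_min, ppm_max, freq) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 2 ||
      n_points != round(n_points))
    stopf("invalid 'n_points': must be a single integer >= 2 (got %s)",
          deparse(n_points))
  if (!is.numeric(freq) || length(freq) != 1 || freq <= 0)
    stopf("invalid 'freq': spectrometer frequency must be > 0 MHz (got %s)",
          deparse(freq))
  if (!is.numeric(ppm_min) || !is.numeric(ppm_max) || ppm_max <= ppm_min)
    stopf("inverted bounds: 'ppm_max' (%s) must exceed 'ppm_min' (%s)",
          deparse(ppm_max), deparse(ppm_min))
  structure(
    list(n_points = as.integer(n_points),
         ppm_min = as.numeric(ppm_min),
         ppm_max = as.numeric(ppm_max),
         spectrometer_freq = as.numeric(freq),
         dppm = (ppm_max - ppm_min) / (n_points - 1)),
    class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d points, %.4g to %.4g ppm @ %g MHz (d = %.4g ppm)\n",
              x$n_points, x$ppm_min, x$ppm_max, x$spectrometer_freq, x$dppm))
  invisible(x)
}

#' Grid values of a spectral axis
#'
#' @param axis a `spectral_axis`.
#' @return `ppm_values`: numeric vector of length `n_points`, ascending.
#'   `hz_offsets`: the same positions expressed in Hz
#'   (`ppm * spectrometer_freq`).
#' @export
ppm_values <- function(axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  seq(axis$ppm_min, axis$ppm_max, length.out = axis$n_points)
}

#' @rdname ppm_values
#' @export
hz_offsets <- function(axis) ppm_values(axis) * axis$spectrometer_freq

#' Default full-scale and desk-scale axes
#'
#' The full-scale axis covers the signal-bearing region -0.32 to 10.2 ppm with
#' 46,000 points; `desk_axis()` is the 4,600-point reduction used by the
#' desk-scale replication protocol (same bounds, 10x coarser).
#'
#' @param freq spectrometer frequency in MHz.
#' @export
default_axis <- function(freq = 400) make_axis(46000L, -0.32, 10.2, freq)

#' @rdname default_axis
#' @export
desk_axis <- function(freq = 400) make_axis(4600L, -0.32, 10.2, freq)

# nearest grid index (1-based) for a ppm position
axis_index <- function(axis, ppm) {
  i <- round((ppm - axis$ppm_min) / axis$dppm) + 1
  pmin(pmax(i, 1L), axis$n_points)
}

axes_compatible <- function(a, b) {
  a$n_points == b$n_points &&
    isTRUE(all.equal(a$ppm_min, b$ppm_min)) &&
    isTRUE(all.equal(a$ppm_max, b$ppm_max))
}
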