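# Reading and writing spectra and spin-model tables.
#
# Two external formats are supported:
#   * JCAMP-DX, restricted to the dialects that cover reference 1D spectra:
#     ##XYDATA=(X++(Y..Y)) with plain (AFFN) numbers, and
#     ##PEAK TABLE=(XY..XY).  The package's own writer emits the former at
#     full double precision so write -> read round-trips exactly.
#   * a tab-separated spin-model (peak-list) table with header
#     name  ppm  j_hz  protons  linewidth_hz, one row per multiplet,
#     `j_hz` a semicolon-separated coupling list ("" for a singlet).

#' Write a spectrum as a minimal JCAMP-DX file
#'
#' Emits an `##XYDATA=(X++(Y..Y))` record in ppm with full double precision.
#'
#' @param spec a [spectrum_record()].
#' @param path output file.
#' @param title optional `##TITLE` value.
#' @export
write_jcamp <- function(spec, path, title = "fieldlift spectrum") {
  stopifnot(inherits(spec, "spectrum_record"))
  ax <- spec$axis
  n_per_line <- 6L
  y <- spec$intensities
  x <- ppm_values(ax)
  starts <- seq(1L, ax$n_points, by = n_per_line)
  body <- vapply(starts, function(s) {
    e <- min(s + n_per_line - 1L, ax$n_points)
    paste(c(sprintf("%.17g", x[s]), sprintf("%.17g", y[s:e])), collapse = " ")
  }, character(1))
  writeLines(c(
    sprintf("##TITLE=%s", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    sprintf("##.OBSERVE FREQUENCY=%.17g", ax$spectrometer_freq),
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    sprintf("##FIRSTX=%.17g", ax$ppm_min),
    sprintf("##LASTX=%.17g", ax$ppm_max),
    sprintf("##NPOINTS=%d", ax$n_points),
    "##XYDATA=(X++(Y..Y))",
    body,
    "##END="), path)
  invisible(path)
}

jcamp_field <- function(headers, key) {
  hit <- headers[toupper(names(headers)) == toupper(key)]
  if (length(hit)) hit[[1]] else NULL
}

parse_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^##TITLE", lines[1]))
    stopf("parse error in '%s' at line 1: not a JCAMP-DX file (missing ##TITLE)",
          path)
  headers <- list(); mode <- NULL
  xy_x <- numeric(0); xy_y <- list(); peaks <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "##")) {
      kv <- sub("^##", "", ln)
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      if (toupper(key) == "XYDATA") { mode <- "xy"; next }
      if (toupper(key) == "PEAK TABLE") { mode <- "peaks"; peaks <- list(); next }
      if (toupper(key) == "END") { mode <- NULL; next }
      headers[[key]] <- val
      mode <- NULL
      next
    }
    if (identical(mode, "xy")) {
      vals <- suppressWarnings(as.numeric(strsplit(ln, "[ \t,]+")[[1]]))
      if (anyNA(vals) || length(vals) < 2)
        stopf("parse error in '%s' at line %d: bad XYDATA row '%s'", path, i, ln)
      xy_x <- c(xy_x, vals[1])
      xy_y[[length(xy_y) + 1L]] <- vals[-1]
    } else if (identical(mode, "peaks")) {
      for (pair in strsplit(ln, ";")[[1]]) {
        vals <- suppressWarnings(as.numeric(strsplit(trimws(pair), "[ \t,]+")[[1]]))
        if (anyNA(vals) || length(vals) != 2)
          stopf("parse error in '%s' at line %d: bad PEAK TABLE entry '%s'",
                path, i, pair)
        peaks[[length(peaks) + 1L]] <- vals
      }
    }
  }
  list(headers = headers, xy_x = xy_x, xy_y = xy_y, peaks = peaks)
}

#' Read an external spectrum and resample it onto an axis
#'
#' Accepts JCAMP-DX files in the `##XYDATA=(X++(Y..Y))` or
#' `##PEAK TABLE=(XY..XY)` dialects.  The x axis may be stored in PPM or in
#' HZ (converted using `##.OBSERVE FREQUENCY`); ascending or descending
#' storage are both accepted.  Continuous data are linearly interpolated onto
#' `axis`; grid points outside the source range are set to zero.  Peak-table
#' sticks are deposited at the nearest grid point.
#'
#' @param path JCAMP-DX file.
#' @param axis target [make_axis()].
#' @return a [spectrum_record()] with provenance recording the source file,
#'   its frequency and its original grid size.
#' @export
read_external_spectrum <- function(path, axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  p <- parse_jcamp(path)
  freq <- jcamp_field(p$headers, ".OBSERVE FREQUENCY")
  if (is.null(freq))
    stopf("format error in '%s': missing required field '.OBSERVE FREQUENCY'",
          path)
  freq <- as.numeric(freq)
  xunits <- toupper(jcamp_field(p$headers, "XUNITS") %||% "PPM")
  to_ppm <- function(x) if (xunits == "HZ") x / freq else x
  grid <- ppm_values(axis)
  if (length(p$xy_x)) {
    # reconstruct the full x vector: each row gives the x of its first y
    npt <- as.numeric(jcamp_field(p$headers, "NPOINTS") %||% NA)
    lens <- lengths(p$xy_y)
    n <- sum(lens)
    if (!is.na(npt) && npt != n)
      stopf("format error in '%s': NPOINTS=%d but %d y values found",
            path, npt, n)
    firstx <- as.numeric(jcamp_field(p$headers, "FIRSTX") %||% p$xy_x[1])
    lastx <- as.numeric(jcamp_field(p$headers, "LASTX") %||% NA)
    if (is.na(lastx))
      stopf("format error in '%s': missing required field 'LASTX'", path)
    x <- to_ppm(seq(firstx, lastx, length.out = n))
    y <- unlist(p$xy_y, use.names = FALSE)
    if (x[1] > x[n]) { x <- rev(x); y <- rev(y) }   # normalize orientation
    out <- stats::approx(x, y, xout = grid, yleft = 0, yright = 0,
                         ties = "ordered")$y
  } else if (!is.null(p$peaks)) {
    out <- numeric(axis$n_points)
    for (pk in p$peaks) {
      ppm <- to_ppm(pk[1])
      if (ppm >= axis$ppm_min && ppm <= axis$ppm_max) {
        i <- axis_index(axis, ppm)
        out[i] <- out[i] + pk[2]
      }
    }
  } else {
    stopf("format error in '%s': no XYDATA or PEAK TABLE block found", path)
  }
  spectrum_record(axis, out, provenance = list(
    source = path, source_freq_mhz = freq,
    source_points = if (length(p$xy_x)) sum(lengths(p$xy_y)) else length(p$peaks)))
}

#' Read spin models from a tab-separated peak-list table
#'
#' The documented text format for user-supplied metabolite models: a header
#' row `name  ppm  j_hz  protons  linewidth_hz`, then one row per multiplet.
#' `j_hz` lists couplings separated by semicolons and is empty for a singlet.
#' Rows sharing a `name` are collected into one [spin_model()].
#'
#' @param path TSV file.
#' @return list of [spin_model()] objects, in first-appearance order.
#' @export
read_spin_models <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "character",
                                         "numeric", "numeric"))
  need <- c("name", "ppm", "j_hz", "protons", "linewidth_hz")
  if (!all(need %in% names(df)))
    stopf("format error in '%s': missing column(s) %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  lapply(unique(df$name), function(nm) {
    rows <- df[df$name == nm, , drop = FALSE]
    spin_model(nm, lapply(seq_len(nrow(rows)), function(i) {
      j <- rows$j_hz[i]
      j <- if (nzchar(trimws(j))) as.numeric(strsplit(j, ";")[[1]]) else numeric(0)
      multiplet(rows$ppm[i], j, rows$protons[i], rows$linewidth_hz[i])
    }))
  })
}
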