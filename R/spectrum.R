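# 2D spectrum container: a real amplitude matrix (13C rows x 1H columns)
# plus per-dimension axis headers. Positions at the API surface are always
# ppm, never grid points; ppm axes run high -> low with increasing index,
# the standard NMR display convention.

#' Define one spectral axis
#'
#' @param sfrq_MHz spectrometer frequency of the nucleus on this axis (MHz)
#' @param ppm_max,ppm_min chemical-shift window (ppm); `ppm_max > ppm_min`
#' @param npoints number of grid points (>= 2)
#' @return an object of class `"spectrum_axis"`
#' @export
spectrum_axis <- function(sfrq_MHz, ppm_max, ppm_min, npoints) {
  stopifnot(sfrq_MHz > 0, npoints >= 2)
  if (ppm_max <= ppm_min) {
    stop_docklink("spectrum_axis: ppm_max must exceed ppm_min")
  }
  structure(
    list(sfrq_MHz = sfrq_MHz, ppm_max = ppm_max, ppm_min = ppm_min,
         npoints = as.integer(npoints)),
    class = "spectrum_axis"
  )
}

#' ppm value of every grid point on an axis (strictly decreasing)
#' @param axis a [spectrum_axis()]
#' @return numeric vector of length `npoints`
#' @export
axis_ppm <- function(axis) {
  seq(axis$ppm_max, axis$ppm_min, length.out = axis$npoints)
}

# ppm separation between adjacent grid points (positive)
axis_step <- function(axis) {
  (axis$ppm_max - axis$ppm_min) / (axis$npoints - 1L)
}

# nearest grid index for a ppm value; NA outside the window
axis_index <- function(axis, ppm) {
  idx <- round((axis$ppm_max - ppm) / axis_step(axis)) + 1L
  idx[idx < 1L | idx > axis$npoints] <- NA_integer_
  as.integer(idx)
}

#' Construct a 2D spectrum grid
#'
#' @param data numeric matrix of amplitudes, `npoints_C` rows by
#'   `npoints_H` columns
#' @param axis_C,axis_H axis definitions from [spectrum_axis()] for the
#'   13C (rows) and 1H (columns) dimensions
#' @return an object of class `"spectrum_grid"`
#' @export
spectrum_grid <- function(data, axis_C, axis_H) {
  stopifnot(is.matrix(data), inherits(axis_C, "spectrum_axis"),
            inherits(axis_H, "spectrum_axis"))
  if (nrow(data) != axis_C$npoints || ncol(data) != axis_H$npoints) {
    stop_docklink("spectrum_grid: matrix dimensions do not match axis headers")
  }
  structure(list(data = data, axis_C = axis_C, axis_H = axis_H),
            class = "spectrum_grid")
}

#' Default acquisition grid for simulated methyl spectra
#'
#' 256 x 512 points over 2 ppm (13C) x 0.8 ppm (1H) at a 750 MHz
#' instrument: resolves 0.03 / 0.4 ppm doublet splittings with more than
#' five points per linewidth at typical methyl linewidths.
#'
#' @param sfrq_h_MHz proton frequency (MHz)
#' @param center_H,center_C window centres (ppm)
#' @return list with elements `axis_C` and `axis_H`
#' @export
default_grid <- function(sfrq_h_MHz = 750, center_H = 0.7, center_C = 12) {
  list(
    axis_C = spectrum_axis(carbon_frequency(sfrq_h_MHz),
                           center_C + 1, center_C - 1, 256L),
    axis_H = spectrum_axis(sfrq_h_MHz, center_H + 0.4, center_H - 0.4, 512L)
  )
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("2D spectrum: %d (13C) x %d (1H) points\n",
              x$axis_C$npoints, x$axis_H$npoints))
  cat(sprintf("  13C: %.3f .. %.3f ppm at %.2f MHz\n",
              x$axis_C$ppm_max, x$axis_C$ppm_min, x$axis_C$sfrq_MHz))
  cat(sprintf("  1H:  %.4f .. %.4f ppm at %.2f MHz\n",
              x$axis_H$ppm_max, x$axis_H$ppm_min, x$axis_H$sfrq_MHz))
  cat(sprintf("  amplitude range: [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Write / read a spectrum as a text matrix with a JSON sidecar header
#'
#' The matrix goes to `<path>` as whitespace-separated full-precision text
#' (one 13C row per line) and the axis headers to `<path>.json`. The pair
#' round-trips bit-exactly.
#'
#' @param spec a [spectrum_grid()]
#' @param path file path for the matrix; the header is written to
#'   `paste0(path, ".json")`
#' @return `path`, invisibly
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_grid"))
  lines <- apply(spec$data, 1L, function(row) paste(format_full(row), collapse = " "))
  writeLines(lines, path)
  hdr <- list(
    axis_C = spec$axis_C[c("sfrq_MHz", "ppm_max", "ppm_min", "npoints")],
    axis_H = spec$axis_H[c("sfrq_MHz", "ppm_max", "ppm_min", "npoints")]
  )
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  hdr_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(hdr_path)) {
    stop_docklink("read_spectrum: missing matrix or JSON header for ", path)
  }
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  ax <- function(h) spectrum_axis(h$sfrq_MHz, h$ppm_max, h$ppm_min, h$npoints)
  mat <- as.matrix(utils::read.table(path, header = FALSE,
                                     colClasses = "numeric"))
  dimnames(mat) <- NULL
  spectrum_grid(mat, ax(hdr$axis_C), ax(hdr$axis_H))
}

#' Robust spectral noise estimate
#'
#' Median-absolute-deviation estimate of the per-point amplitude noise.
#' Peaks occupy a negligible fraction of the grid, so the MAD of the whole
#' plane is a serviceable stand-in for the RMS of a signal-free region.
#'
#' @param spec a [spectrum_grid()]
#' @return estimated noise standard deviation (amplitude units)
#' @export
estimate_noise <- function(spec) {
  stopifnot(inherits(spec, "spectrum_grid"))
  stats::mad(as.numeric(spec$data), center = 0)
}
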