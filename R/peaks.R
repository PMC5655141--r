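# Peak measurement and doublet analysis for slow-exchange spectra.
#
# Intensities are interpolated peak heights, not volumes: the 3-point
# parabolic method applied independently along each dimension, mirroring
# the standard peak-height readout of interactive NMR analysis software.

new_peak <- function(assignment, dH, dC, height, edge = FALSE) {
  data.frame(assignment = assignment, dH = dH, dC = dC,
             height = height, edge = edge, stringsAsFactors = FALSE)
}

# parabola through (-1, ym), (0, y0), (1, yp): vertex offset (index units)
# and interpolated height increment relative to y0
parabolic_vertex <- function(ym, y0, yp) {
  denom <- ym + yp - 2 * y0
  if (denom >= 0) return(list(dx = 0, dh = 0))  # not locally concave
  dx <- (ym - yp) / (2 * denom)
  dh <- -((yp - ym)^2) / (8 * denom)
  list(dx = dx, dh = dh)
}

#' Measure a peak by parabolic interpolation
#'
#' Finds the maximum grid point within a ppm search radius of the supplied
#' approximate position, then refines position and height by independent
#' 3-point parabolic interpolation along the 1H and 13C dimensions. The
#' interpolated height is the node value plus both one-dimensional parabola
#' corrections (separable quadratic approximation of the peak top).
#'
#' @param spectrum a [spectrum_grid()]
#' @param dH,dC approximate peak position (ppm)
#' @param assignment probe label used in messages and output
#' @param radius_H,radius_C search radius per axis (ppm)
#' @return one-row data.frame: `assignment`, `dH`, `dC` (refined, ppm),
#'   `height`, `edge` (TRUE when the maximum sat on the grid edge and the
#'   height was taken without interpolation)
#' @export
measure_peak_intensity <- function(spectrum, dH, dC, assignment = "peak",
                                   radius_H = 0.02, radius_C = 0.2) {
  stopifnot(inherits(spectrum, "spectrum_grid"))
  ax_H <- spectrum$axis_H
  ax_C <- spectrum$axis_C
  jc <- axis_index(ax_C, dC)
  jh <- axis_index(ax_H, dH)
  if (is.na(jc) || is.na(jh)) {
    stop_docklink(sprintf("measure_peak_intensity: position of '%s' lies outside the spectrum axes", assignment))
  }
  rc <- max(1L, round(radius_C / axis_step(ax_C)))
  rh <- max(1L, round(radius_H / axis_step(ax_H)))
  ic <- max(1L, jc - rc):min(ax_C$npoints, jc + rc)
  ih <- max(1L, jh - rh):min(ax_H$npoints, jh + rh)
  sub <- spectrum$data[ic, ih, drop = FALSE]
  w <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
  pc <- ic[w[1L]]
  ph <- ih[w[2L]]

  on_spectrum_edge <- pc == 1L || pc == ax_C$npoints ||
    ph == 1L || ph == ax_H$npoints
  if (!on_spectrum_edge) {
    y0 <- spectrum$data[pc, ph]
    is_local_max <- y0 >= spectrum$data[pc - 1L, ph] &&
      y0 >= spectrum$data[pc + 1L, ph] &&
      y0 >= spectrum$data[pc, ph - 1L] &&
      y0 >= spectrum$data[pc, ph + 1L]
    if (!is_local_max) {
      stop_docklink(sprintf("measure_peak_intensity: peak not found for '%s' within the search radius", assignment))
    }
    vc <- parabolic_vertex(spectrum$data[pc - 1L, ph], y0,
                           spectrum$data[pc + 1L, ph])
    vh <- parabolic_vertex(spectrum$data[pc, ph - 1L], y0,
                           spectrum$data[pc, ph + 1L])
    ppm_c <- axis_ppm(ax_C)[pc] - vc$dx * axis_step(ax_C)
    ppm_h <- axis_ppm(ax_H)[ph] - vh$dx * axis_step(ax_H)
    return(new_peak(assignment, ppm_h, ppm_c, y0 + vc$dh + vh$dh))
  }
  # maximum on the spectrum edge: no interpolation, flagged
  new_peak(assignment, axis_ppm(ax_H)[ph], axis_ppm(ax_C)[pc],
           spectrum$data[pc, ph], edge = TRUE)
}

#' Combined 1H/13C chemical-shift difference
#'
#' `sqrt(ddH^2 + (w * ddC)^2)` with the conventional methyl carbon weight
#' `w = 0.25`.
#'
#' @param ddH,ddC shift differences per axis (ppm); vectorized
#' @param carbon_weight dimensionless carbon weight
#' @return combined shift difference (ppm)
#' @export
combined_csp <- function(ddH, ddC, carbon_weight = 0.25) {
  sqrt(ddH^2 + (carbon_weight * ddC)^2)
}

#' Shift perturbation between two measured peaks
#'
#' @param a,b one-row peak data.frames (as from [measure_peak_intensity()]);
#'   differences are `a - b`
#' @param carbon_weight dimensionless carbon weight
#' @return list of class `"shift_perturbation"`: `ddH`, `ddC`, `combined`,
#'   `carbon_weight` (ppm)
#' @export
shift_perturbation <- function(a, b, carbon_weight = 0.25) {
  ddH <- a$dH - b$dH
  ddC <- a$dC - b$dC
  structure(list(ddH = ddH, ddC = ddC,
                 combined = combined_csp(ddH, ddC, carbon_weight),
                 carbon_weight = carbon_weight),
            class = "shift_perturbation")
}

#' Pair full-length peaks into slow-exchange doublets
#'
#' Matching follows the overlay logic used to assign conformations: the
#' full-length peak that coincides with an isolated-domain reference peak is
#' the undocked (U) member; the nearest remaining full-length peak within
#' the doublet window is the docked (D) member. Assignment is greedy in
#' order of increasing combined shift difference, each full-length peak used
#' at most once.
#'
#' @param full_length_peaks,reference_peaks peak data.frames with columns
#'   `assignment`, `dH`, `dC`, `height`
#' @param match_tolerance combined-shift tolerance (ppm) for U matching
#' @param doublet_window combined-shift window (ppm) for the D search
#' @param carbon_weight carbon weight of the combined shift metric
#' @return data.frame of class `"peak_doublets"`, one row per reference
#'   peak: positions and heights of U and D members, D-minus-U offsets, and
#'   a `status` of `"doublet"`, `"singlet"` (no D peak; excluded from
#'   population math) or `"overlapped"` (ambiguous D candidates; excluded by
#'   default). Reference peaks with no U match are attached as attribute
#'   `"unmatched"`.
#' @export
pair_doublets <- function(full_length_peaks, reference_peaks,
                          match_tolerance = 0.02, doublet_window = 0.2,
                          carbon_weight = 0.25) {
  fl <- full_length_peaks
  ref <- reference_peaks
  stopifnot(nrow(ref) >= 1L, nrow(fl) >= 1L)

  d <- outer(seq_len(nrow(ref)), seq_len(nrow(fl)),
             function(i, j) combined_csp(ref$dH[i] - fl$dH[j],
                                         ref$dC[i] - fl$dC[j], carbon_weight))
  # greedy U assignment in order of increasing combined shift
  u_of <- rep(NA_integer_, nrow(ref))
  fl_used <- rep(FALSE, nrow(fl))
  ord <- order(d)
  for (k in ord) {
    if (d[k] > match_tolerance) break
    i <- (k - 1L) %% nrow(ref) + 1L
    j <- (k - 1L) %/% nrow(ref) + 1L
    if (is.na(u_of[i]) && !fl_used[j]) {
      u_of[i] <- j
      fl_used[j] <- TRUE
    }
  }

  rows <- vector("list", nrow(ref))
  for (i in seq_len(nrow(ref))) {
    if (is.na(u_of[i])) next
    j <- u_of[i]
    # D candidates: unused full-length peaks inside the doublet window
    # around the reference position
    cand <- which(!fl_used)
    if (length(cand)) {
      dd <- combined_csp(ref$dH[i] - fl$dH[cand], ref$dC[i] - fl$dC[cand],
                         carbon_weight)
      cand <- cand[dd <= doublet_window]
      dd <- dd[dd <= doublet_window]
    }
    status <- if (!length(cand)) "singlet"
              else if (length(cand) > 1L) "overlapped" else "doublet"
    jd <- if (length(cand)) cand[which.min(dd)] else NA_integer_
    if (!is.na(jd)) fl_used[jd] <- TRUE
    rows[[i]] <- data.frame(
      probe = ref$assignment[i],
      U_dH = fl$dH[j], U_dC = fl$dC[j], I_U = fl$height[j],
      D_dH = if (is.na(jd)) NA_real_ else fl$dH[jd],
      D_dC = if (is.na(jd)) NA_real_ else fl$dC[jd],
      I_D = if (is.na(jd)) NA_real_ else fl$height[jd],
      csp_U = d[i, j],
      status = status,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    stop_docklink("pair_doublets: no reference peak found a full-length match within match_tolerance")
  }
  out$ddH <- out$D_dH - out$U_dH
  out$ddC <- out$D_dC - out$U_dC
  class(out) <- c("peak_doublets", "data.frame")
  attr(out, "unmatched") <- ref$assignment[is.na(u_of)]
  out
}

#' Slow-exchange timescale bound from doublet shift separations
#'
#' Converts each shift separation to Hz on its own axis
#' (`dnu = ddppm * sfrq_MHz`), takes the smallest nonzero separation, and
#' reports the slow-exchange lifetime bound `tau = 1/dnu_min` together with
#' the stricter conventional bound `1/(2*pi*dnu_min)`. Interconversion
#' slower than `tau` is consistent with resolved doublets.
#'
#' @param ddH,ddC shift separations (ppm); vectors, recycled
#' @param sfrq_h_MHz 1H spectrometer frequency (MHz)
#' @param sfrq_c_MHz 13C frequency (MHz); defaults to the 13C Larmor
#'   frequency on the same instrument
#' @return list of class `"exchange_bound"`: `dnu_min_Hz`, `axis` ("1H" or
#'   "13C"), `tau_s`, `tau_2pi_s`
#' @export
exchange_timescale_bound <- function(ddH, ddC = NULL, sfrq_h_MHz = 750,
                                     sfrq_c_MHz = carbon_frequency(sfrq_h_MHz)) {
  dnu <- c(abs(ddH) * sfrq_h_MHz,
           if (!is.null(ddC)) abs(ddC) * sfrq_c_MHz)
  axes <- c(rep("1H", length(ddH)),
            if (!is.null(ddC)) rep("13C", length(ddC)))
  keep <- is.finite(dnu) & dnu > 0
  if (!any(keep)) {
    stop_docklink("exchange_timescale_bound: no shift separation; exchange regime indeterminate")
  }
  dnu <- dnu[keep]
  axes <- axes[keep]
  k <- which.min(dnu)
  structure(
    list(dnu_min_Hz = dnu[k], axis = axes[k],
         tau_s = 1 / dnu[k], tau_2pi_s = 1 / (2 * pi * dnu[k])),
    class = "exchange_bound"
  )
}

#' @export
print.exchange_bound <- function(x, ...) {
  cat(sprintf("slow-exchange bound: dnu_min = %.2f Hz (%s axis)\n",
              x$dnu_min_Hz, x$axis))
  cat(sprintf("  tau = 1/dnu        = %.1f ms\n", 1e3 * x$tau_s))
  cat(sprintf("  tau = 1/(2 pi dnu) = %.1f ms (stricter convention)\n",
              1e3 * x$tau_2pi_s))
  invisible(x)
}

#' Read / write Sparky-style peak lists
#'
#' Whitespace-separated columns `Assignment  w1(ppm)  w2(ppm)  Data Height`
#' with `w1` the 13C shift and `w2` the 1H shift; lines starting with `#`
#' are comments.
#'
#' @param path file path
#' @return data.frame with columns `assignment`, `dC`, `dH`, `height`
#' @export
read_sparky <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # drop a possible column-header line
  lines <- lines[!grepl("^Assignment", lines, ignore.case = TRUE)]
  if (!length(lines)) {
    return(data.frame(assignment = character(), dC = numeric(),
                      dH = numeric(), height = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(parts, length, integer(1L)) < 4L)
  if (length(bad)) {
    stop_docklink("read_sparky: malformed peak-list line ", bad[1L])
  }
  data.frame(
    assignment = vapply(parts, `[[`, character(1L), 1L),
    dC = as.numeric(vapply(parts, `[[`, character(1L), 2L)),
    dH = as.numeric(vapply(parts, `[[`, character(1L), 3L)),
    height = as.numeric(vapply(parts, `[[`, character(1L), 4L)),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_sparky
#' @param peaks peak data.frame with columns `assignment`, `dC`, `dH`,
#'   `height`
#' @export
write_sparky <- function(peaks, path) {
  header <- c("# Sparky-style peak list: w1 = 13C (ppm), w2 = 1H (ppm)",
              "Assignment  w1(ppm)  w2(ppm)  Data Height")
  body <- sprintf("%s  %s  %s  %s", peaks$assignment,
                  format_full(peaks$dC), format_full(peaks$dH),
                  format_full(peaks$height))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Quantify doublets from a full-length / reference spectrum pair
#'
#' Convenience wrapper: measures the reference peak of every probe, the
#' candidate U and D peaks in the full-length spectrum (at the supplied
#' undocked position and docked offset), and pairs them with
#' [pair_doublets()].
#'
#' @param full_length,reference [spectrum_grid()] objects sharing axes
#' @param probes data.frame with columns `probe`, `dH`, `dC` (undocked
#'   position, ppm) and `ddH`, `ddC` (approximate docked offsets, ppm)
#' @param match_tolerance,doublet_window,carbon_weight see [pair_doublets()]
#' @param radius_H,radius_C see [measure_peak_intensity()]
#' @return a `"peak_doublets"` data.frame
#' @export
quantify_doublets <- function(full_length, reference, probes,
                              match_tolerance = 0.02, doublet_window = 0.2,
                              carbon_weight = 0.25,
                              radius_H = 0.02, radius_C = 0.2) {
  stopifnot(all(c("probe", "dH", "dC", "ddH", "ddC") %in% names(probes)))
  ref_peaks <- do.call(rbind, lapply(seq_len(nrow(probes)), function(i) {
    measure_peak_intensity(reference, probes$dH[i], probes$dC[i],
                           probes$probe[i], radius_H, radius_C)
  }))
  fl_peaks <- do.call(rbind, lapply(seq_len(nrow(probes)), function(i) {
    rbind(
      measure_peak_intensity(full_length, probes$dH[i], probes$dC[i],
                             paste0(probes$probe[i], "_U"),
                             radius_H, radius_C),
      measure_peak_intensity(full_length, probes$dH[i] + probes$ddH[i],
                             probes$dC[i] + probes$ddC[i],
                             paste0(probes$probe[i], "_D"),
                             radius_H, radius_C)
    )
  }))
  pair_doublets(fl_peaks, ref_peaks, match_tolerance, doublet_window,
                carbon_weight)
}
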