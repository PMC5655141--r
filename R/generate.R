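# Seeded synthetic-data generators. These define the study conditions the
# downstream estimators are validated against: slow-exchange methyl doublets
# with 1H/13C splittings of order 0.03/0.4 ppm, single-site nucleotide
# titrations at 20-80 uM cell concentrations, and construct panels lying on
# a known two-state linkage curve. Every generator is deterministic under a
# fixed integer seed.

#' Default methyl probe set
#'
#' Three well-separated Ile-d1-like probes inside the default grid window.
#' The docked-minus-undocked shift offsets default to 0.03 ppm (1H) and
#' 0.4 ppm (13C), the magnitude characteristic of domain docking;
#' linewidths default to 15 Hz on both axes.
#'
#' @param n number of probes (1..6)
#' @param ddH,ddC docked-state shift offsets (ppm), recycled across probes
#' @param lw_Hz full linewidth at half maximum (Hz), both axes
#' @param amplitude total doublet amplitude per probe
#' @return data.frame with one row per probe
#' @export
default_probes <- function(n = 3L, ddH = 0.03, ddC = 0.4, lw_Hz = 15,
                           amplitude = 1) {
  stopifnot(n >= 1L, n <= 6L)
  base_H <- c(0.50, 0.75, 0.95, 0.60, 0.85, 0.45)
  base_C <- c(11.3, 11.9, 12.5, 12.2, 11.6, 12.35)
  data.frame(
    probe = paste0("I", seq_len(n)),
    dH = base_H[seq_len(n)],
    dC = base_C[seq_len(n)],
    ddH = rep_len(ddH, n),
    ddC = rep_len(ddC, n),
    lw_H_Hz = rep_len(lw_Hz, n),
    lw_C_Hz = rep_len(lw_Hz, n),
    amplitude = rep_len(amplitude, n),
    stringsAsFactors = FALSE
  )
}

#' Ground truth for a simulated two-state conformational ensemble
#'
#' @param docked_fraction true docked population p_D in \[0, 1\]
#' @param probes probe table as from [default_probes()]: columns `probe`,
#'   `dH`, `dC` (undocked position, ppm), `ddH`, `ddC` (docked-minus-undocked
#'   offsets, ppm), `lw_H_Hz`, `lw_C_Hz` (linewidths, Hz), `amplitude`
#' @param noise_sigma standard deviation of additive Gaussian noise per grid
#'   point (amplitude units; >= 0)
#' @param seed integer seed for the noise stream, or NULL
#' @return object of class `"ensemble_truth"`
#' @export
ensemble_ground_truth <- function(docked_fraction, probes = default_probes(),
                                  noise_sigma = 0.02, seed = NULL) {
  stopifnot(is.data.frame(probes), nrow(probes) >= 1L)
  need <- c("probe", "dH", "dC", "ddH", "ddC", "lw_H_Hz", "lw_C_Hz", "amplitude")
  missing_cols <- setdiff(need, names(probes))
  if (length(missing_cols)) {
    stop_docklink("ensemble_ground_truth: probe table lacks column(s) ",
                  paste(missing_cols, collapse = ", "))
  }
  if (docked_fraction < 0 || docked_fraction > 1) {
    stop_docklink("ensemble_ground_truth: docked_fraction must lie in [0, 1]")
  }
  if (any(probes$lw_H_Hz <= 0) || any(probes$lw_C_Hz <= 0)) {
    stop_docklink("ensemble_ground_truth: linewidths must be positive")
  }
  if (noise_sigma < 0) {
    stop_docklink("ensemble_ground_truth: noise_sigma must be >= 0")
  }
  structure(
    list(docked_fraction = docked_fraction, probes = probes,
         noise_sigma = noise_sigma, seed = seed),
    class = "ensemble_truth"
  )
}

# unit-height 1D absorption Lorentzian; fwhm in ppm
lorentz1d <- function(x, x0, fwhm) 1 / (1 + (2 * (x - x0) / fwhm)^2)

# add one 2D Lorentzian peak (product lineshape) of given height to `mat`
add_peak <- function(mat, axis_C, axis_H, dC, dH, fwhm_C, fwhm_H, height) {
  mat + height * outer(lorentz1d(axis_ppm(axis_C), dC, fwhm_C),
                       lorentz1d(axis_ppm(axis_H), dH, fwhm_H))
}

check_inside <- function(axis, ppm, probe, what) {
  margin <- 3 * axis_step(axis)
  if (ppm > axis$ppm_max - margin || ppm < axis$ppm_min + margin) {
    stop_docklink(sprintf(
      "generate_spectrum_pair: %s peak of probe '%s' (%.4f ppm) falls outside the grid window (need >= 3 points of margin)",
      what, probe, ppm))
  }
  invisible(TRUE)
}

#' Simulate a full-length / isolated-domain spectrum pair
#'
#' The full-length spectrum carries, per probe, an undocked (U) peak at the
#' reference position with height proportional to `1 - p_D` and a docked (D)
#' peak offset by (`ddH`, `ddC`) with height proportional to `p_D` — the
#' slow-exchange doublet. The reference spectrum carries only the U-position
#' peak at full amplitude, emulating the isolated domain. Peaks are 2D
#' Lorentzians (product of 1D absorption Lorentzians); i.i.d. Gaussian noise
#' of sd `noise_sigma` is added to every grid point of both planes.
#'
#' @param truth an [ensemble_ground_truth()]
#' @param grid list with `axis_C`, `axis_H` as from [default_grid()]
#' @return list of class `"spectrum_pair"` with elements `full_length`,
#'   `reference` (both [spectrum_grid()]) and `truth`
#' @export
generate_spectrum_pair <- function(truth, grid = default_grid()) {
  stopifnot(inherits(truth, "ensemble_truth"))
  axis_C <- grid$axis_C
  axis_H <- grid$axis_H
  p <- truth$docked_fraction
  pr <- truth$probes

  for (i in seq_len(nrow(pr))) {
    check_inside(axis_H, pr$dH[i], pr$probe[i], "U")
    check_inside(axis_C, pr$dC[i], pr$probe[i], "U")
    check_inside(axis_H, pr$dH[i] + pr$ddH[i], pr$probe[i], "D")
    check_inside(axis_C, pr$dC[i] + pr$ddC[i], pr$probe[i], "D")
  }

  fl <- matrix(0, axis_C$npoints, axis_H$npoints)
  ref <- matrix(0, axis_C$npoints, axis_H$npoints)
  for (i in seq_len(nrow(pr))) {
    fwhm_H <- pr$lw_H_Hz[i] / axis_H$sfrq_MHz   # Hz -> ppm
    fwhm_C <- pr$lw_C_Hz[i] / axis_C$sfrq_MHz
    # U peak: amplitudes partition as (1 - p) : p, summing to `amplitude`
    fl <- add_peak(fl, axis_C, axis_H, pr$dC[i], pr$dH[i],
                   fwhm_C, fwhm_H, (1 - p) * pr$amplitude[i])
    fl <- add_peak(fl, axis_C, axis_H, pr$dC[i] + pr$ddC[i],
                   pr$dH[i] + pr$ddH[i], fwhm_C, fwhm_H, p * pr$amplitude[i])
    ref <- add_peak(ref, axis_C, axis_H, pr$dC[i], pr$dH[i],
                    fwhm_C, fwhm_H, pr$amplitude[i])
  }

  if (truth$noise_sigma > 0) {
    npts <- length(fl)
    noise <- with_seed(truth$seed,
                       stats::rnorm(2L * npts, sd = truth$noise_sigma))
    fl <- fl + matrix(noise[seq_len(npts)], nrow(fl), ncol(fl))
    ref <- ref + matrix(noise[npts + seq_len(npts)], nrow(ref), ncol(ref))
  }

  structure(
    list(full_length = spectrum_grid(fl, axis_C, axis_H),
         reference = spectrum_grid(ref, axis_C, axis_H),
         truth = truth),
    class = "spectrum_pair"
  )
}

#' Simulate a single-site ITC titration
#'
#' Injection heats follow the exact single-site forward model
#' ([itc_injection_heats()]) with the displaced-volume dilution convention,
#' plus a constant per-injection dilution heat and i.i.d. Gaussian heat
#' noise.
#'
#' @param n site stoichiometry
#' @param Kd dissociation constant (M)
#' @param dH binding enthalpy (kcal/mol)
#' @param cell_conc protein concentration in the cell before titration (M)
#' @param syringe_conc titrant concentration in the syringe (M);
#'   must exceed `cell_conc`
#' @param cell_volume calorimeter cell volume (L)
#' @param injection_volumes per-injection volumes (L), length >= 5
#' @param temperature temperature (K)
#' @param heat_noise_sigma Gaussian heat noise sd (ucal)
#' @param dilution_heat constant heat of dilution per injection (ucal)
#' @param seed integer seed, or NULL
#' @return an [itc_titration()] with the ground truth attached as
#'   attribute `"truth"`
#' @export
generate_itc_titration <- function(n = 1, Kd, dH,
                                   cell_conc = 40e-6,
                                   syringe_conc = 0.4e-3,
                                   cell_volume = 200e-6,
                                   injection_volumes = rep(1.5e-6, 25L),
                                   temperature = 298,
                                   heat_noise_sigma = 0,
                                   dilution_heat = 0,
                                   seed = NULL) {
  if (syringe_conc <= cell_conc) {
    stop_docklink("generate_itc_titration: titrant belongs in the syringe (syringe_conc must exceed cell_conc)")
  }
  if (length(injection_volumes) < 5L) {
    stop_docklink("generate_itc_titration: need at least 5 injections")
  }
  q <- itc_injection_heats(n = n, Kd = Kd, dH = dH,
                           cell_conc = cell_conc,
                           syringe_conc = syringe_conc,
                           cell_volume = cell_volume,
                           injection_volumes = injection_volumes)
  noise <- if (heat_noise_sigma > 0) {
    with_seed(seed, stats::rnorm(length(q), sd = heat_noise_sigma))
  } else {
    rep(0, length(q))
  }
  tit <- itc_titration(cell_conc = cell_conc, syringe_conc = syringe_conc,
                       cell_volume = cell_volume, temperature = temperature,
                       injections = data.frame(volume_L = injection_volumes,
                                               heat_ucal = q + dilution_heat + noise))
  ratio_final <- molar_ratio(tit)[length(injection_volumes)]
  if (ratio_final <= 1) {
    warning("generate_itc_titration: schedule never exceeds molar ratio 1; the fit will be ill-conditioned",
            call. = FALSE)
  }
  attr(tit, "truth") <- list(n = n, Kd = Kd, dH = dH,
                             dilution_heat = dilution_heat,
                             heat_noise_sigma = heat_noise_sigma, seed = seed)
  tit
}

#' Simulate a construct panel on a known thermodynamic linkage curve
#'
#' For each docked fraction `p`, emits a construct state with docking free
#' energy `-ln(p/(1-p))` (RT units) and binding free energy
#' `ln(p*Kd_D + (1-p)*Kd_U)` plus Gaussian scatter of sd `scatter_sd`
#' (RT units) on the binding axis.
#'
#' @param params a [linkage_parameters()] holding the pure-state constants
#'   `Kd_D`, `Kd_U` (M)
#' @param docked_fractions docked populations, each strictly inside (0, 1)
#' @param scatter_sd Gaussian scatter on `dG_bind/RT` (dimensionless)
#' @param seed integer seed, or NULL
#' @param nucleotide label stored on every row ("ATP" or "ADP")
#' @return data.frame of class `"construct_panel"` with columns `construct`,
#'   `nucleotide`, `p_D`, `dG_dock_RT`, `dG_bind_RT`, `Kd_M`; the generating
#'   parameters are attached as attribute `"truth"`
#' @export
generate_construct_panel <- function(params, docked_fractions, scatter_sd = 0,
                                     seed = NULL, nucleotide = "ATP") {
  stopifnot(inherits(params, "linkage_parameters"))
  if (any(docked_fractions <= 0 | docked_fractions >= 1)) {
    stop_docklink("generate_construct_panel: docked fractions must lie strictly in (0, 1); the docking free energy diverges at 0 and 1")
  }
  if (scatter_sd < 0) stop_docklink("generate_construct_panel: scatter_sd must be >= 0")
  m <- length(docked_fractions)
  scatter <- if (scatter_sd > 0) {
    with_seed(seed, stats::rnorm(m, sd = scatter_sd))
  } else {
    rep(0, m)
  }
  dg_dock <- docking_free_energy(docked_fractions)
  dg_bind <- log(ensemble_kd(params, docked_fractions)) + scatter
  panel <- data.frame(
    construct = sprintf("synthetic_%02d", seq_len(m)),
    nucleotide = rep_len(nucleotide, m),
    p_D = docked_fractions,
    dG_dock_RT = dg_dock,
    dG_bind_RT = dg_bind,
    Kd_M = exp(dg_bind),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("construct_panel", "data.frame")
  attr(panel, "truth") <- list(Kd_D = params$Kd_D, Kd_U = params$Kd_U,
                               scatter_sd = scatter_sd, seed = seed)
  panel
}

#' Write a ground-truth manifest as JSON next to a synthetic dataset
#'
#' @param truth an `"ensemble_truth"` or any list of generator parameters
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_manifest <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
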