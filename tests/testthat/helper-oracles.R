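# Independent oracles and fixture builders shared across tests.
# Everything here is deliberately written without reusing the package's
# computational path for the quantity it checks.

# Brute-force single-site equilibrium: bisection on free ligand under mass
# action, C = B_t * Lf / (Kd + Lf) with B_t = n * P_t and Lf = L_t - C.
oracle_complex <- function(n, Kd, P_t, L_t, tol = 1e-15) {
  vapply(seq_along(P_t), function(i) {
    Bt <- n * P_t[i]
    f <- function(Lf) (Bt * Lf / (Kd + Lf)) - (L_t[i] - Lf)
    if (L_t[i] <= 0) return(0)
    uniroot(f, c(0, L_t[i]), tol = tol * max(L_t[i], 1e-12))$root
  }, numeric(1L)) -> Lf
  L_t - Lf
}

# Oracle injection heats on the same displaced-volume bookkeeping, with the
# equilibrium solved by bisection instead of the quadratic root.
oracle_heats <- function(n, Kd, dH, cell_conc, syringe_conc, cell_volume,
                         injection_volumes) {
  dv <- cumsum(injection_volumes)
  f <- dv / (2 * cell_volume)
  P <- cell_conc * (1 - f) / (1 + f)
  L <- syringe_conc * (dv / cell_volume) / (1 + f)
  PL <- oracle_complex(n, Kd, P, L)
  Q <- cell_volume * dH * PL * 1e9
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (injection_volumes / cell_volume) * (Q + Qprev) / 2
}

# Analytic height of the full-length plane at an exact ppm position:
# sum over every Lorentzian peak the generator laid down (noiseless).
analytic_height <- function(truth, grid, at_dH, at_dC) {
  pr <- truth$probes
  p <- truth$docked_fraction
  total <- 0
  for (i in seq_len(nrow(pr))) {
    fwhm_H <- pr$lw_H_Hz[i] / grid$axis_H$sfrq_MHz
    fwhm_C <- pr$lw_C_Hz[i] / grid$axis_C$sfrq_MHz
    lz <- function(x, x0, w) 1 / (1 + (2 * (x - x0) / w)^2)
    total <- total +
      (1 - p) * pr$amplitude[i] * lz(at_dH, pr$dH[i], fwhm_H) *
        lz(at_dC, pr$dC[i], fwhm_C) +
      p * pr$amplitude[i] * lz(at_dH, pr$dH[i] + pr$ddH[i], fwhm_H) *
        lz(at_dC, pr$dC[i] + pr$ddC[i], fwhm_C)
  }
  total
}

# End-to-end docked-population measurement on one simulated spectrum pair.
quantify_pair_populations <- function(docked_fraction, noise_sigma, seed,
                                      probes = default_probes()) {
  truth <- ensemble_ground_truth(docked_fraction, probes,
                                 noise_sigma = noise_sigma, seed = seed)
  pair <- generate_spectrum_pair(truth)
  doublets <- quantify_doublets(pair$full_length, pair$reference, probes)
  estimate_populations(doublets, noise_sigma = noise_sigma)
}

# docked fractions spaced uniformly in docking free energy over [-3, 3] RT:
# the recovery-experiment design for the linkage fit
linkage_design_fractions <- function(k = 6L) {
  1 / (1 + exp(seq(-3, 3, length.out = k)))
}
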