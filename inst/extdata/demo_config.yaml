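# Demo run config: a BiP-like synthetic panel, simulated and analysed
# end to end. Documented key set; unknown keys are rejected.
#
# mode: simulate (write synthetic data only), analyze (consume the files
#       named under inputs:), or all (simulate then analyse the result)
mode: all
seed: 42

# slow-exchange doublet spectra: docked fraction, docked-minus-undocked
# shift offsets (ppm), linewidths (Hz), additive noise sd (amplitude units)
spectra:
  docked_fraction: 0.53
  n_probes: 3
  ddH_ppm: 0.03
  ddC_ppm: 0.4
  linewidth_Hz: 15
  noise_sigma: 0.02
  sfrq_h_MHz: 750

# one single-site titration per construct/nucleotide pair
itc:
  - construct: BiP_FL
    nucleotide: ATP
    Kd_uM: 0.80
    dH_kcal: 11.4
    cell_conc_uM: 40
    syringe_conc_mM: 0.4
    cell_volume_uL: 200
    n_injections: 25
    injection_volume_uL: 1.5
    heat_noise_ucal: 0.15
  - construct: BiP_FL
    nucleotide: ADP
    Kd_uM: 5.73
    dH_kcal: -7.4
    cell_conc_uM: 60
    syringe_conc_mM: 0.4
    cell_volume_uL: 200
    n_injections: 25
    injection_volume_uL: 1.5
    heat_noise_ucal: 0.15

# construct panel on a known two-state linkage curve (ATP-like constants)
panel:
  Kd_D_nM: 1
  Kd_U_nM: 800
  docked_fractions: [0.08, 0.25, 0.45, 0.53, 0.68, 0.85]
  scatter_sd: 0.3
  nucleotide: ATP

# doublet pairing tolerances (combined 1H/13C shift, ppm)
tolerances:
  match_tolerance_ppm: 0.02
  doublet_window_ppm: 0.2
  carbon_weight: 0.25
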