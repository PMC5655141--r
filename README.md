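# docklink

Quantitative analysis of two-state conformational ensembles in Hsp70-family
chaperones (BiP and relatives), for structural biologists working with
methyl-NMR and isothermal titration calorimetry (ITC) data.

ATP-bound BiP co-exists in solution as two slowly interconverting
conformations — domain-docked (D) and domain-undocked (U). In slow exchange
every reporter methyl gives one peak per conformation, and the docked
population follows directly from the peak intensities:

    p_D = I_D / (I_D + I_U) x 100%

ITC on the same constructs yields the nucleotide-binding thermodynamics,

    dG = R T ln Kd,        -T dS = dG - dH,

and the two measurements are coupled by a two-state thermodynamic linkage
model in which the observed dissociation constant is the population-weighted
sum of the pure-state constants:

    Kd_obs = p_D Kd_D + (1 - p_D) Kd_U
    dG(binding)/RT = ln(p_D Kd_D + p_U Kd_U)
    dG(docking)/RT = -ln(p_D / (1 - p_D))

The package implements the full chain — peak-height measurement by parabolic
interpolation, doublet pairing against isolated-domain reference spectra,
population and error estimation, exchange-timescale bounds, single-site ITC
isotherm fitting, and the linkage fit for `(Kd_D, Kd_U)` — together with a
seeded synthetic-data generator (2D Lorentzian doublet spectra, titrations,
construct panels) so every stage is testable against known ground truth, and
an end-to-end pipeline driver with byte-stable outputs.

## Worked example

Simulate a three-doublet methyl spectrum pair at 53% docked with realistic
noise, quantify it, and bound the exchange timescale:

```r
library(docklink)

probes <- default_probes()                       # 3 Ile-like reporters
truth  <- ensemble_ground_truth(0.53, probes, noise_sigma = 0.02, seed = 42)
pair   <- generate_spectrum_pair(truth)

doublets <- quantify_doublets(pair$full_length, pair$reference, probes)
estimate_populations(doublets, noise_sigma = 0.02)
#> docked population: p_D = 53.3 +/- 1.4 % (p_U = 46.7 %)
#>   3 doublet(s); SD = 0.56 %, propagated = 1.38 % (max taken)

exchange_timescale_bound(doublets$ddH, doublets$ddC, sfrq_h_MHz = 750)
#> slow-exchange bound: dnu_min = 21.90 Hz (1H axis)
#>   tau = 1/dnu        = 45.7 ms
#>   tau = 1/(2 pi dnu) = 7.3 ms (stricter convention)
```

The estimate recovers the generating 53% within its own error bar, and the
resolved 0.03 ppm 1H splitting implies interconversion slower than ~46 ms.

Fit a single-site titration at the tight-binding ATP condition
(Kd = 0.80 uM, dH = 11.4 kcal/mol, 40 uM cell protein):

```r
tit <- generate_itc_titration(Kd = 0.80e-6, dH = 11.4,
                              heat_noise_sigma = 0.07, seed = 42)
fit_single_site(tit)
#> single-site ITC fit
#>   n     = 0.999 +/- 0.007
#>   Kd    = 7.044e-07 +/- 7.4e-08 M (0.704 uM)
#>   dH    = 11.337 +/- 0.173 kcal/mol
#>   q_dil = 0.022 ucal/injection
#>   c-value = 56.7
#>   dG = -8.39, -TdS = -19.73 kcal/mol at 298 K
```

Kd and dH come back within the fit's standard errors of the ground truth;
`dG` and `-TdS` are derived at 298 K with `R = 1.987e-3` kcal/(mol K).

Fit the pure-state constants across a scattered six-state construct panel:

```r
params <- linkage_parameters(Kd_D = 1.5e-6, Kd_U = 7e-6)   # ADP-like contrast
panel  <- generate_construct_panel(params,
            1 / (1 + exp(seq(-3, 3, length.out = 6))),     # p_D 0.047..0.953
            scatter_sd = 0.3, seed = 42)
fit_state_constants(panel)
#> two-state linkage fit (log-Kd least squares)
#>   Kd_D = 1.887e-06 M (1.89e+03 nM)
#>   Kd_U = 7.347e-06 M (7.35e+03 nM)
#>   6 states, docked-fraction spread 0.91
#>   RMS residual 0.171 (RT units of dG_bind)
```

With 0.3 RT of scatter on six points the constants come back within ~25%
of truth on this seed; `plot()` on the fit draws the theoretical linkage
curve through the panel points.

An entire simulate → quantify → fit → link run is one call on the shipped
demo config (see `inst/extdata/demo_config.yaml` for the documented keys):

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "docklink"),
             out_dir = "demo_run", seed = 7)
```

which writes spectra, a population report, a thermodynamics ledger, the
construct panel and the linkage fit under `demo_run/`, plus a run manifest;
reruns with the same seed are byte-identical. A thin CLI wrapper lives at
`inst/scripts/docklink.R`.

## Package layout

| | |
|---|---|
| `R/generate.R` | seeded synthetic spectra, titrations, panels |
| `R/spectrum.R`, `R/peaks.R` | spectrum container + I/O, peak measurement, doublet pairing, CSP, exchange bound |
| `R/populations.R` | docked-fraction estimation and error model |
| `R/itc.R` | single-site forward model, isotherm fit, state functions, thermodynamics ledger |
| `R/linkage.R` | docking free energies, ensemble Kd, linkage curve and fit |
| `R/pipeline.R` | config-driven end-to-end runs, validation, manifests |
| `vignettes/two-state-ensemble-analysis.Rmd` | model assumptions, parameter choices, identifiability analysis, limitations |
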