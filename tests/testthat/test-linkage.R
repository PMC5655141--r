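test_that("docking free energy follows -ln(p/(1-p)) with an exact inverse", {
  expect_equal(docking_free_energy(0.5), 0)
  expect_equal(docking_free_energy(0.53), -log(0.53 / 0.47), tolerance = 1e-12)
  expect_equal(docking_free_energy(0.53), -0.1201, tolerance = 1e-3)
  # about -0.0712 kcal/mol at 298 K
  expect_equal(docking_free_energy(0.53) * R_KCAL * 298, -0.0711,
               tolerance = 1e-3)
  p <- seq(0.02, 0.98, by = 0.04)
  expect_equal(docking_free_energy(p), -docking_free_energy(1 - p),
               tolerance = 1e-12)
  expect_equal(population_from_docking_energy(docking_free_energy(p)), p,
               tolerance = 1e-12)
  expect_error(docking_free_energy(0), "strictly")
  expect_error(docking_free_energy(1), "strictly")
})

test_that("ensemble Kd interpolates the pure states and the printed constants", {
  params <- linkage_parameters(1e-9, 800e-9)
  expect_equal(ensemble_kd(params, 1), 1e-9)
  expect_equal(ensemble_kd(params, 0), 800e-9)
  expect_equal(ensemble_kd(params, 0.53), 0.53 * 1e-9 + 0.47 * 800e-9,
               tolerance = 1e-15)
  expect_equal(ensemble_kd(params, 0.53) * 1e9, 376.53, tolerance = 1e-10)
  same <- linkage_parameters(5e-7, 5e-7)
  expect_equal(ensemble_kd(same, c(0, 0.3, 1)), rep(5e-7, 3L))
  expect_error(ensemble_kd(params, 1.1), "\\[0, 1\\]")
  expect_error(linkage_parameters(0, 1e-6), "positive")
})

test_that("ensemble Kd is bounded and monotone over random parameter sweeps", {
  set.seed(99)
  for (i in 1:25) {
    kd1 <- 10^runif(1, -10, -4)
    kd2 <- 10^runif(1, -10, -4)
    params <- linkage_parameters(kd1, kd2)
    p <- sort(runif(20))
    kobs <- ensemble_kd(params, p)
    expect_true(all(kobs >= min(kd1, kd2) - 1e-25))
    expect_true(all(kobs <= max(kd1, kd2) + 1e-25))
    d <- diff(kobs)
    if (kd1 < kd2) expect_true(all(d <= 1e-25)) else expect_true(all(d >= -1e-25))
  }
})

test_that("the theoretical curve hits its midpoint and asymptotes", {
  params <- linkage_parameters(1e-9, 800e-9)
  mid <- theoretical_curve(params, 0)
  expect_equal(mid$dG_bind_RT, log((1e-9 + 800e-9) / 2), tolerance = 1e-12)
  asym <- theoretical_curve(params, c(-20, 20))
  expect_equal(asym$dG_bind_RT[1L], log(1e-9), tolerance = 1e-6)
  expect_equal(asym$dG_bind_RT[2L], log(800e-9), tolerance = 1e-6)
  curve_df <- theoretical_curve(params)
  expect_true(all(diff(curve_df$dG_bind_RT) >= 0))   # Kd_D < Kd_U
  expect_equal(range(curve_df$p_D), c(population_from_docking_energy(8),
                                      population_from_docking_energy(-8)),
               tolerance = 1e-12)
})

test_that("noiseless panels return the generating constants exactly", {
  params <- linkage_parameters(1.5e-6, 7e-6)
  panel <- generate_construct_panel(params, linkage_design_fractions())
  fit <- fit_state_constants(panel)
  expect_lt(abs(coef(fit)[["Kd_D"]] - 1.5e-6) / 1.5e-6, 1e-6)
  expect_lt(abs(coef(fit)[["Kd_U"]] - 7e-6) / 7e-6, 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("unidentifiable and weakly identified panels are reported", {
  panel_same <- data.frame(p_D = c(0.5, 0.5), Kd_M = c(1e-6, 2e-6))
  expect_error(fit_state_constants(panel_same), "not separately identifiable")
  panel_narrow <- data.frame(p_D = c(0.45, 0.5, 0.55),
                             Kd_M = c(1.1e-6, 1.0e-6, 0.9e-6))
  expect_warning(fit_state_constants(panel_narrow), "spread")
})

test_that("fully undocked states enter the fit at p_D = 0", {
  params <- linkage_parameters(1.5e-6, 7e-6)
  panel <- generate_construct_panel(params, c(0.2, 0.5, 0.8))
  panel2 <- rbind(as.data.frame(panel)[, c("construct", "nucleotide", "p_D", "Kd_M")],
                  data.frame(construct = "undocked_state", nucleotide = "ADP",
                             p_D = NA_real_, Kd_M = 7e-6))
  panel2$undocked <- c(FALSE, FALSE, FALSE, TRUE)
  fit <- fit_state_constants(panel2)
  expect_equal(coef(fit)[["Kd_U"]], 7e-6, tolerance = 1e-6)
  expect_equal(coef(fit)[["Kd_D"]], 1.5e-6, tolerance = 1e-5)
  # missing p_D without the flag is an error
  panel_bad <- panel2
  panel_bad$undocked <- FALSE
  expect_error(fit_state_constants(panel_bad), "undocked flag")
})

test_that("a panel anchored on the printed measurements brackets the observed constants", {
  # measured docked fractions and affinities (ATP-bound full-length
  # chaperone plus docked-shifted variants), fully undocked ADP-like row
  # entering at p_D = 0
  panel <- data.frame(
    construct = c("wt", "variant_docked", "variant_more_docked", "undocked"),
    p_D = c(0.53, 0.67, 0.85, NA),
    undocked = c(FALSE, FALSE, FALSE, TRUE),
    Kd_M = c(0.80e-6, 0.55e-6, 0.30e-6, 5.73e-6),
    stringsAsFactors = FALSE
  )
  fit <- fit_state_constants(panel)
  cf <- coef(fit)
  # on monotone decreasing data the fit orders the constants correctly,
  # places the undocked asymptote inside the observed range (a least-squares
  # compromise) and extrapolates the docked constant below the most-docked
  # observation -- the same behaviour as the published fit, whose docked
  # constant sits far below every measured Kd
  expect_lt(cf[["Kd_D"]], cf[["Kd_U"]])
  expect_gte(cf[["Kd_U"]], min(panel$Kd_M))
  expect_lte(cf[["Kd_U"]], max(panel$Kd_M))
  expect_lte(cf[["Kd_D"]], min(panel$Kd_M))
})

test_that("noisy-panel recovery is consistent and tightens with panel size", {
  params <- linkage_parameters(1.5e-6, 7e-6)
  med_err <- function(k, seeds) {
    errs <- vapply(seeds, function(s) {
      pan <- generate_construct_panel(params, linkage_design_fractions(k),
                                      scatter_sd = 0.3, seed = s)
      cf <- coef(fit_state_constants(pan))
      max(abs(log(cf[["Kd_D"]] / 1.5e-6)), abs(log(cf[["Kd_U"]] / 7e-6)))
    }, numeric(1L))
    median(errs)
  }
  expect_lt(med_err(12L, 1:40), med_err(6L, 1:40))
})

test_that("the affinity-weighted convention is available but distinct", {
  params <- linkage_parameters(1e-9, 800e-9)
  kd_sum <- ensemble_kd(params, 0.5)
  kd_aff <- ensemble_kd(params, 0.5, weight_affinities = TRUE)
  expect_equal(kd_sum, 400.5e-9, tolerance = 1e-12)
  expect_lt(kd_aff, kd_sum)  # harmonic vs arithmetic weighting
})

test_that("construct panel CSV round-trips including undocked flags", {
  params <- linkage_parameters(1.5e-6, 7e-6)
  panel <- as.data.frame(generate_construct_panel(params, c(0.3, 0.7)))
  panel$undocked <- FALSE
  panel <- rbind(panel[, c("construct", "nucleotide", "p_D", "undocked", "Kd_M")],
                 data.frame(construct = "apo", nucleotide = "ADP",
                            p_D = NA_real_, undocked = TRUE, Kd_M = 5.7e-6))
  path <- file.path(tempdir(), "panel.csv")
  write_panel_csv(panel, path)
  back <- read_panel_csv(path)
  expect_equal(back$p_D[1:2], panel$p_D[1:2], tolerance = 1e-12)
  expect_true(back$undocked[3L])
  expect_equal(back$Kd_M, panel$Kd_M, tolerance = 1e-12)
  expect_error(fit_state_constants(back), NA)
  unlink(path)
})
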