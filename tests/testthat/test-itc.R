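default_schedule <- function() rep(1.5e-6, 25L)

test_that("forward model obeys its limiting cases", {
  q0 <- itc_injection_heats(1, 1e-6, 0, 40e-6, 0.4e-3, 200e-6, default_schedule())
  expect_equal(q0, rep(0, 25L))
  q_weak <- itc_injection_heats(1, 10, 10, 40e-6, 0.4e-3, 200e-6, default_schedule())
  expect_true(all(abs(q_weak) < 1e-3))
  expect_error(itc_injection_heats(1, -1, 10, 40e-6, 0.4e-3, 200e-6,
                                   default_schedule()), "positive")
})

test_that("quadratic-root heats match brute-force mass-action bisection", {
  set.seed(404)
  for (rep in 1:12) {
    n <- runif(1, 0.7, 1.5)
    Kd <- 10^runif(1, -9, -4)
    dH <- runif(1, -15, 15)
    P0 <- runif(1, 2e-5, 8e-5)
    L0 <- runif(1, 1e-4, 4e-4)
    vols <- runif(sample(10:30, 1), 0.5e-6, 3e-6)
    q <- itc_injection_heats(n, Kd, dH, P0, L0, 2e-4, vols)
    q_oracle <- oracle_heats(n, Kd, dH, P0, L0, 2e-4, vols)
    expect_lt(max(abs(q - q_oracle)) / max(abs(q_oracle)), 1e-9)
  }
})

test_that("noiseless titrations are recovered to high precision", {
  for (truth in list(c(Kd = 0.8e-6, dH = 11.4), c(Kd = 5.73e-6, dH = -7.4),
                     c(Kd = 1.15e-6, dH = 14.7))) {
    tit <- generate_itc_titration(Kd = truth[["Kd"]], dH = truth[["dH"]],
                                  cell_conc = 60e-6)
    fit <- fit_single_site(tit)
    expect_lt(abs(coef(fit)[["Kd"]] - truth[["Kd"]]) / truth[["Kd"]], 1e-6)
    expect_lt(abs(coef(fit)[["dH"]] - truth[["dH"]]) / abs(truth[["dH"]]), 1e-6)
    expect_lt(abs(coef(fit)[["n"]] - 1), 1e-6)
  }
})

test_that("dilution-heat offsets are absorbed by the nuisance parameter", {
  tit <- generate_itc_titration(Kd = 1e-6, dH = 9, dilution_heat = 0.4)
  fit <- fit_single_site(tit)
  expect_equal(coef(fit)[["q_dil"]], 0.4, tolerance = 1e-4)
  expect_lt(abs(coef(fit)[["Kd"]] - 1e-6) / 1e-6, 1e-5)
})

test_that("null data yield near-zero enthalpy and an unconstrained Kd flag", {
  inj <- data.frame(volume_L = default_schedule(),
                    heat_ucal = rep(0.2, 25L))
  tit <- itc_titration(40e-6, 0.4e-3, 200e-6, injections = inj)
  fit <- suppressWarnings(fit_single_site(tit))
  expect_lt(abs(coef(fit)[["dH"]]), 0.05)
  expect_false(fit$kd_constrained)
})

test_that("seeded noisy titrations across c-values recover Kd and dH", {
  # c = n P0 / Kd spanning ~[10, 500]
  set.seed(77)
  kds <- 10^runif(50, log10(40e-6 / 500), log10(40e-6 / 10))
  errs <- t(vapply(seq_along(kds), function(i) {
    q <- itc_injection_heats(1, kds[i], 11.4, 40e-6, 0.4e-3, 200e-6,
                             default_schedule())
    tit <- generate_itc_titration(Kd = kds[i], dH = 11.4,
                                  heat_noise_sigma = 0.01 * max(abs(q)),
                                  seed = 1000L + i)
    cf <- coef(fit_single_site(tit))
    c(abs(cf[["Kd"]] - kds[i]) / kds[i], abs(cf[["dH"]] - 11.4) / 11.4)
  }, numeric(2L)))
  expect_lt(median(errs[, 1L]), 0.05)
  expect_lt(median(errs[, 2L]), 0.02)
})

test_that("state functions reproduce the printed full-length and NBD ledgers", {
  # ATP rows: Kd in uM, dH / printed dG / printed -TdS in kcal/mol
  fl <- derive_state_functions(0.80e-6, 11.4)
  expect_equal(fl$dG, -8.3, tolerance = 0.1 / 8.3)
  expect_equal(fl$minus_TdS, -19.7, tolerance = 0.1 / 19.7)
  nbd <- derive_state_functions(7.41e-6, 12.3)
  expect_equal(nbd$dG, -7.0, tolerance = 0.1 / 7.0)
  expect_equal(nbd$minus_TdS, -19.3, tolerance = 0.1 / 19.3)
  # identities and degenerate cases
  expect_equal(derive_state_functions(1, 5)$dG, 0)
  expect_error(derive_state_functions(-1e-6, 5), "positive")
  expect_error(derive_state_functions(1e-6, 5, temperature = 0), "positive")
})

test_that("Kd <-> dG round trip is exact and monotone", {
  kds <- 10^seq(-9, -3, length.out = 13)
  dg <- derive_state_functions(kds, 0)$dG
  expect_equal(exp(dg / (R_KCAL * 298)), kds, tolerance = 1e-12)
  expect_true(all(diff(dg) > 0))
})

test_that("the thermodynamic ledger recomputes, flags inconsistencies, and rejects duplicates", {
  rows <- data.frame(
    construct = c("FL", "FL", "NBD_1_413", "NBD_1_413", "NBD_1_417", "NBD_1_417"),
    nucleotide = c("ATP", "ADP", "ATP", "ADP", "ATP", "ADP"),
    Kd_uM = c(0.80, 5.73, 7.41, 5.27, 1.15, 3.94),
    dH = c(11.4, -7.4, 12.3, -7.4, 14.7, -6.4),
    dG_printed = c(-8.3, -7.1, -7.0, -7.2, -8.1, -7.4),
    mTdS_printed = c(-19.7, 0.3, -19.3, 0.2, -22.3, 1.0),
    stringsAsFactors = FALSE
  )
  tab <- thermo_table(rows)
  expect_equal(tab$flag[1:4], rep("", 4L))
  # the two linker-bearing NBD rows disagree with their own Kd/dH arithmetic
  expect_equal(tab$flag[5:6], rep("inconsistent", 2L))
  expect_equal(tab$mTdS[6L], -1.0, tolerance = 0.05 / 1)
  expect_equal(tab$mTdS, tab$dG - tab$dH, tolerance = 1e-12)

  expect_error(thermo_table(rows[c(1, 1), ]), "duplicate")
  empty <- thermo_table(rows[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("construct", "ANP", "Kd_uM", "dG", "dH", "mTdS") %in%
                    names(empty)))

  path <- file.path(tempdir(), "thermo.csv")
  write_thermo_table(tab, path)
  pres <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(pres$dG[1L], -8.3)
  expect_equal(pres$mTdS[1L], -19.7)
  unlink(path)
})

test_that("ITC CSV dialect round-trips and reports missing headers by key", {
  tit <- generate_itc_titration(Kd = 1e-6, dH = 10, heat_noise_sigma = 0.2,
                                seed = 3L)
  path <- file.path(tempdir(), "titration.csv")
  write_itc_csv(tit, path)
  back <- read_itc_csv(path)
  expect_equal(back$cell_conc, tit$cell_conc)
  expect_equal(back$injections$heat_ucal, tit$injections$heat_ucal)
  # CRLF tolerance
  writeLines(paste0(readLines(path), "\r"), path)
  back2 <- read_itc_csv(path)
  expect_equal(back2$injections$volume_L, tit$injections$volume_L)
  # missing temperature header named in the failure
  lines <- readLines(path)
  writeLines(lines[!grepl("^#temperature_K=", lines)], path)
  expect_error(read_itc_csv(path), "temperature_K")
  unlink(path)
})

test_that("low c-value titrations trigger the poorly-constrained warning", {
  tit <- generate_itc_titration(Kd = 5e-5, dH = 10, cell_conc = 20e-6,
                                syringe_conc = 4e-4)
  expect_warning(fit_single_site(tit), "poorly constrained")
})
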