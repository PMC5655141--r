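make_single_peak_spectrum <- function(dH, dC, fwhm_H_ppm, fwhm_C_ppm,
                                      height = 1, grid = default_grid()) {
  lz <- function(x, x0, w) 1 / (1 + (2 * (x - x0) / w)^2)
  mat <- height * outer(lz(axis_ppm(grid$axis_C), dC, fwhm_C_ppm),
                        lz(axis_ppm(grid$axis_H), dH, fwhm_H_ppm))
  spectrum_grid(mat, grid$axis_C, grid$axis_H)
}

test_that("a maximum sitting on a grid node is returned verbatim", {
  g <- default_grid()
  dH <- axis_ppm(g$axis_H)[250L]
  dC <- axis_ppm(g$axis_C)[120L]
  sp <- make_single_peak_spectrum(dH, dC, 0.02, 0.08)
  pk <- measure_peak_intensity(sp, dH, dC)
  expect_equal(pk$height, 1, tolerance = 1e-12)
  expect_equal(pk$dH, dH, tolerance = 1e-12)
  expect_equal(pk$dC, dC, tolerance = 1e-12)
  expect_false(pk$edge)
})

test_that("parabolic interpolation recovers off-node Lorentzian heights within 1%", {
  g <- default_grid()
  step_H <- (g$axis_H$ppm_max - g$axis_H$ppm_min) / (g$axis_H$npoints - 1)
  step_C <- (g$axis_C$ppm_max - g$axis_C$ppm_min) / (g$axis_C$npoints - 1)
  # off-node along one dimension at a time: moderate offsets stay within
  # 1% at five points per linewidth; the worst case (half a step) needs six
  for (frac in c(0.3, 0.17)) {
    dH <- axis_ppm(g$axis_H)[250L] + frac * step_H
    dC <- axis_ppm(g$axis_C)[120L]
    sp <- make_single_peak_spectrum(dH, dC, 5 * step_H, 5 * step_C)
    pk <- measure_peak_intensity(sp, dH, dC)
    expect_equal(pk$height, 1, tolerance = 0.01)
    expect_equal(pk$dH, dH, tolerance = step_H / 4)
  }
  dH <- axis_ppm(g$axis_H)[250L] + 0.5 * step_H
  sp <- make_single_peak_spectrum(dH, axis_ppm(g$axis_C)[120L],
                                  6 * step_H, 6 * step_C)
  pk <- measure_peak_intensity(sp, dH, axis_ppm(g$axis_C)[120L])
  expect_equal(pk$height, 1, tolerance = 0.01)
  # worst case with both dimensions half a step off: the two 1D parabola
  # deficits add, so the error roughly doubles
  dH <- axis_ppm(g$axis_H)[250L] + 0.5 * step_H
  dC <- axis_ppm(g$axis_C)[120L] + 0.5 * step_C
  sp <- make_single_peak_spectrum(dH, dC, 5 * step_H, 5 * step_C)
  pk <- measure_peak_intensity(sp, dH, dC)
  expect_equal(pk$height, 1, tolerance = 0.025)
  expect_equal(pk$dC, dC, tolerance = step_C / 4)
})

test_that("measured heights are linear in peak amplitude", {
  g <- default_grid()
  a <- make_single_peak_spectrum(0.5, 11.3, 0.02, 0.08, height = 2)
  b <- make_single_peak_spectrum(0.8, 12.3, 0.02, 0.08, height = 1)
  sp <- spectrum_grid(a$data + b$data, g$axis_C, g$axis_H)
  h2 <- measure_peak_intensity(sp, 0.5, 11.3)$height
  h1 <- measure_peak_intensity(sp, 0.8, 12.3)$height
  expect_equal(h2 / h1, 2, tolerance = 1e-3)
})

test_that("absent peaks and edge maxima are handled explicitly", {
  g <- default_grid()
  sp <- make_single_peak_spectrum(0.5, 11.3, 0.02, 0.08)
  # far from the peak, the plane is smooth and monotone: no local max
  expect_error(measure_peak_intensity(sp, 0.9, 12.6, "ghost"), "ghost")
  expect_error(measure_peak_intensity(sp, 5, 11.3), "outside")
  # a peak centred on the first 1H column maximises on the grid edge
  edge_sp <- make_single_peak_spectrum(g$axis_H$ppm_max, 11.3, 0.02, 0.08)
  pk <- measure_peak_intensity(edge_sp, g$axis_H$ppm_max, 11.3)
  expect_true(pk$edge)
})

test_that("combined shift difference follows the weighted quadrature", {
  expect_equal(combined_csp(0.03, 0.4), sqrt(0.0009 + 0.01), tolerance = 1e-12)
  expect_equal(combined_csp(0.03, 0), 0.03)
  expect_equal(combined_csp(0, 0), 0)
  a <- data.frame(dH = 1, dC = 10)
  expect_equal(shift_perturbation(a, a)$combined, 0)
  sp <- shift_perturbation(data.frame(dH = 1.03, dC = 10.4),
                           data.frame(dH = 1.00, dC = 10.0))
  expect_equal(sp$combined, 0.104403, tolerance = 1e-5)
})

test_that("identical full-length and reference spectra pair as U-only singlets", {
  pk <- data.frame(assignment = c("I1", "I2"), dH = c(0.5, 0.8),
                   dC = c(11.3, 12.3), height = c(1, 2),
                   stringsAsFactors = FALSE)
  db <- pair_doublets(pk, pk)
  expect_equal(nrow(db), 2L)
  expect_true(all(db$status == "singlet"))
  expect_true(all(is.na(db$I_D)))
  expect_error(estimate_populations(db), "no doublets")
})

test_that("synthetic doublets pair with offsets matching the generator truth", {
  probes <- default_probes()
  pair <- generate_spectrum_pair(ensemble_ground_truth(0.53, probes, noise_sigma = 0))
  db <- quantify_doublets(pair$full_length, pair$reference, probes)
  expect_equal(nrow(db), 3L)
  expect_true(all(db$status == "doublet"))
  expect_equal(db$ddH, probes$ddH, tolerance = 1e-3)
  expect_equal(db$ddC, probes$ddC, tolerance = 1e-2)
})

test_that("ambiguous docked candidates are flagged overlapped and ties resolved by shift", {
  ref <- data.frame(assignment = "I1", dH = 0.5, dC = 11.3, height = 1,
                    stringsAsFactors = FALSE)
  fl <- data.frame(assignment = c("u", "d1", "d2"),
                   dH = c(0.5, 0.52, 0.53), dC = c(11.3, 11.6, 11.7),
                   height = c(0.5, 0.4, 0.3), stringsAsFactors = FALSE)
  db <- pair_doublets(fl, ref)
  expect_equal(db$status, "overlapped")
  expect_error(estimate_populations(db), "no doublets")
  est <- estimate_populations(db, include_overlapped = TRUE)
  expect_equal(est$p_D, 0.4 / 0.9 * 100, tolerance = 1e-10)

  # two reference peaks contending for one full-length peak: nearer wins
  ref2 <- data.frame(assignment = c("A", "B"), dH = c(0.500, 0.505),
                     dC = c(11.3, 11.3), height = c(1, 1),
                     stringsAsFactors = FALSE)
  fl2 <- data.frame(assignment = "x", dH = 0.5, dC = 11.3, height = 1,
                    stringsAsFactors = FALSE)
  db2 <- pair_doublets(fl2, ref2)
  expect_equal(db2$probe, "A")
  expect_equal(attr(db2, "unmatched"), "B")
})

test_that("exchange-timescale bound uses the smallest axis-converted separation", {
  b <- exchange_timescale_bound(0.03, 0.4, sfrq_h_MHz = 750)
  expect_equal(b$dnu_min_Hz, 22.5, tolerance = 1e-12)
  expect_equal(b$tau_s, 1 / 22.5, tolerance = 1e-12)
  expect_equal(b$axis, "1H")
  # carbon separation on the same instrument: 0.4 ppm * 188.6 MHz = 75.4 Hz
  expect_equal(0.4 * carbon_frequency(750), 75.43, tolerance = 1e-3)
  # reciprocal scaling
  b2 <- exchange_timescale_bound(0.06, sfrq_h_MHz = 750)
  expect_equal(b2$tau_s, b$tau_s / 2, tolerance = 1e-12)
  expect_equal(b$tau_2pi_s, b$tau_s / (2 * pi), tolerance = 1e-12)
  expect_error(exchange_timescale_bound(0, 0), "indeterminate")
})

test_that("Sparky-style peak lists round-trip and tolerate comments", {
  pk <- data.frame(assignment = c("I145", "I371"), dC = c(11.32, 12.41),
                   dH = c(0.512, 0.843), height = c(1.25e5, 9.8e4),
                   stringsAsFactors = FALSE)
  path <- file.path(tempdir(), "peaks.list")
  write_sparky(pk, path)
  lines <- readLines(path)
  writeLines(c("# extra comment", lines), path)
  back <- read_sparky(path)
  expect_equal(back, pk)
  writeLines(c(lines, "only three fields"), path)
  expect_error(read_sparky(path), "malformed")
  unlink(path)
})
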