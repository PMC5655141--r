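# End-to-end orchestration: simulate -> quantify -> fit -> link -> report,
# driven by a single YAML config. Identical config + seed give byte-stable
# numeric outputs; every artefact lands under the run directory.

pipeline_known_keys <- list(
  top = c("mode", "seed", "output_dir", "spectra", "itc", "panel",
          "tolerances", "inputs"),
  spectra = c("docked_fraction", "n_probes", "ddH_ppm", "ddC_ppm",
              "linewidth_Hz", "noise_sigma", "sfrq_h_MHz", "amplitude"),
  itc = c("construct", "nucleotide", "n", "Kd_uM", "dH_kcal",
          "cell_conc_uM", "syringe_conc_mM", "cell_volume_uL",
          "n_injections", "injection_volume_uL", "heat_noise_ucal",
          "dilution_heat_ucal"),
  panel = c("Kd_D_nM", "Kd_U_nM", "docked_fractions", "scatter_sd",
            "nucleotide"),
  tolerances = c("match_tolerance_ppm", "doublet_window_ppm",
                 "carbon_weight"),
  inputs = c("full_length_spectrum", "reference_spectrum", "probes_csv",
             "itc_files", "panel_csv")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop_docklink(sprintf("run config: unknown key(s) in %s: %s", where,
                          paste(unknown, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read and validate a pipeline run config
#'
#' The config is a single YAML file; unknown keys anywhere are errors so
#' typos fail fast. See the shipped demo config
#' (`system.file("extdata", "demo_config.yaml", package = "docklink")`) for
#' the documented key set.
#'
#' @param config path to a YAML file, or an equivalent named list
#' @return validated config list of class `"run_config"`
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop_docklink("run config not found: ", config)
    yaml::read_yaml(config)
  } else {
    config
  }
  check_keys(cfg, pipeline_known_keys$top, "top level")
  cfg$mode <- cfg$mode %||% "all"
  if (!cfg$mode %in% c("simulate", "analyze", "all")) {
    stop_docklink("run config: mode must be simulate, analyze or all")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (!is.null(cfg$spectra)) check_keys(cfg$spectra, pipeline_known_keys$spectra, "spectra")
  if (!is.null(cfg$panel)) check_keys(cfg$panel, pipeline_known_keys$panel, "panel")
  if (!is.null(cfg$tolerances)) check_keys(cfg$tolerances, pipeline_known_keys$tolerances, "tolerances")
  if (!is.null(cfg$inputs)) check_keys(cfg$inputs, pipeline_known_keys$inputs, "inputs")
  for (i in seq_along(cfg$itc)) {
    check_keys(cfg$itc[[i]], pipeline_known_keys$itc, sprintf("itc[%d]", i))
  }
  tol <- cfg$tolerances
  cfg$tolerances <- list(
    match_tolerance_ppm = tol$match_tolerance_ppm %||% 0.02,
    doublet_window_ppm = tol$doublet_window_ppm %||% 0.2,
    carbon_weight = tol$carbon_weight %||% 0.25
  )
  if (any(unlist(cfg$tolerances) <= 0)) {
    stop_docklink("run config: every tolerance must be positive")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Validate pipeline inputs without running anything
#'
#' Checks config key conformance, file-format conformance of referenced
#' inputs (spectra headers, peak tables, ITC CSVs, panel CSV), unit sanity
#' and cross-references. Reports, never throws.
#'
#' @param config path to a YAML config or a config list
#' @return data.frame with columns `check`, `status`
#'   (`"pass"`/`"warn"`/`"fail"`) and `message`
#' @export
validate_inputs <- function(config) {
  out <- list()
  note <- function(check, status, message = "") {
    out[[length(out) + 1L]] <<- data.frame(check = check, status = status,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  cfg <- tryCatch(read_run_config(config), error = function(e) e)
  if (inherits(cfg, "error")) {
    note("config", "fail", conditionMessage(cfg))
    return(do.call(rbind, out))
  }
  note("config", "pass", sprintf("mode=%s seed=%d", cfg$mode, cfg$seed))
  if (!is.null(cfg$spectra)) {
    sp <- cfg$spectra
    ok <- (sp$docked_fraction %||% 0.5) >= 0 && (sp$docked_fraction %||% 0.5) <= 1 &&
      (sp$noise_sigma %||% 0) >= 0 && (sp$linewidth_Hz %||% 15) > 0
    note("spectra block", if (ok) "pass" else "fail",
         if (ok) "" else "docked_fraction/noise/linewidth out of range")
  }
  if (cfg$mode %in% c("analyze")) {
    inp <- cfg$inputs
    if (is.null(inp)) {
      note("inputs block", "fail", "analyze mode requires an inputs block")
    } else {
      for (key in c("full_length_spectrum", "reference_spectrum")) {
        p <- inp[[key]]
        if (is.null(p)) next
        if (!file.exists(p) || !file.exists(paste0(p, ".json"))) {
          note(key, "fail", sprintf("missing matrix or JSON header: %s", p))
        } else {
          sp <- tryCatch(read_spectrum(p), error = function(e) e)
          if (inherits(sp, "error")) {
            note(key, "fail", conditionMessage(sp))
          } else {
            sane <- sp$axis_H$ppm_max < 15 && sp$axis_C$ppm_max < 250
            note(key, if (sane) "pass" else "warn",
                 if (sane) "" else "ppm window looks unusual for methyl spectra")
          }
        }
      }
      if (!is.null(inp$probes_csv)) {
        if (!file.exists(inp$probes_csv)) {
          note("probes_csv", "fail", paste("not found:", inp$probes_csv))
        } else {
          pr <- tryCatch(utils::read.csv(inp$probes_csv), error = function(e) e)
          if (inherits(pr, "error")) {
            note("probes_csv", "fail", conditionMessage(pr))
          } else if (anyDuplicated(pr$probe)) {
            note("probes_csv", "warn",
                 paste("duplicate assignment labels:",
                       paste(unique(pr$probe[duplicated(pr$probe)]),
                             collapse = ", ")))
          } else {
            note("probes_csv", "pass")
          }
        }
      }
      for (f in inp$itc_files %||% character()) {
        tit <- tryCatch(read_itc_csv(f), error = function(e) e)
        if (inherits(tit, "error")) {
          note(paste0("itc:", basename(f)), "fail", conditionMessage(tit))
        } else {
          sane <- tit$cell_conc < 1e-2 && tit$syringe_conc < 1
          note(paste0("itc:", basename(f)), if (sane) "pass" else "warn",
               if (sane) "" else "concentrations look implausibly large")
        }
      }
      if (!is.null(inp$panel_csv)) {
        pan <- tryCatch(read_panel_csv(inp$panel_csv), error = function(e) e)
        if (inherits(pan, "error")) {
          note("panel_csv", "fail", conditionMessage(pan))
        } else if (any(!is.finite(pan$Kd_M) | pan$Kd_M <= 0)) {
          note("panel_csv", "fail", "every construct needs a positive Kd")
        } else {
          note("panel_csv", "pass")
        }
      }
    }
  }
  do.call(rbind, out)
}

run_log <- function(con, ...) {
  msg <- sprintf(...)
  message(msg)
  writeLines(msg, con)
}

#' Run the analysis pipeline end to end
#'
#' Executes the stages requested by the config mode: `simulate` writes
#' seeded synthetic spectra, titrations and a construct panel with their
#' ground-truth manifests; `analyze` quantifies docked populations from the
#' spectra, fits every titration, fits the linkage constants across the
#' panel and writes the reports; `all` chains both. A machine-readable run
#' manifest (config hash, seed, stage list, artifact paths) lands at the
#' end. Reruns with the same config and seed are byte-identical.
#'
#' @param config path to a YAML config or a config list (see
#'   [read_run_config()])
#' @param out_dir run directory; created if absent
#' @param seed optional integer overriding the config seed
#' @return (invisibly) list with the run manifest and key results
#'   (`population`, `thermo`, `linkage`)
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))

  config_hash <- {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(unclass(cfg), tmp)
    h <- unname(tools::md5sum(tmp))
    unlink(tmp)
    h
  }
  artifacts <- character()
  stages <- character()
  results <- list()
  add_artifact <- function(path) artifacts <<- c(artifacts, path)

  stage <- function(name, expr) {
    run_log(log_con, "[%s] starting", name)
    res <- tryCatch(expr, error = function(e) {
      run_log(log_con, "[%s] FAILED: %s", name, conditionMessage(e))
      stop_docklink(sprintf("pipeline stage '%s' failed: %s (partial outputs in %s are incomplete)",
                            name, conditionMessage(e), out_dir))
    })
    stages <<- c(stages, name)
    run_log(log_con, "[%s] done", name)
    res
  }

  inputs <- cfg$inputs %||% list()

  if (cfg$mode %in% c("simulate", "all")) {
    stage("simulate-spectra", {
      sp <- cfg$spectra %||% list()
      probes <- default_probes(n = sp$n_probes %||% 3L,
                               ddH = sp$ddH_ppm %||% 0.03,
                               ddC = sp$ddC_ppm %||% 0.4,
                               lw_Hz = sp$linewidth_Hz %||% 15,
                               amplitude = sp$amplitude %||% 1)
      truth <- ensemble_ground_truth(sp$docked_fraction %||% 0.53, probes,
                                     noise_sigma = sp$noise_sigma %||% 0.02,
                                     seed = cfg$seed + 11L)
      pair <- generate_spectrum_pair(truth,
                                     default_grid(sp$sfrq_h_MHz %||% 750))
      dir.create(file.path(out_dir, "spectra"), showWarnings = FALSE)
      write_spectrum(pair$full_length, file.path(out_dir, "spectra", "full_length.txt"))
      write_spectrum(pair$reference, file.path(out_dir, "spectra", "reference.txt"))
      utils::write.csv(probes, file.path(out_dir, "spectra", "probes.csv"),
                       row.names = FALSE, quote = FALSE)
      write_manifest(list(docked_fraction = truth$docked_fraction,
                          noise_sigma = truth$noise_sigma,
                          seed = truth$seed),
                     file.path(out_dir, "spectra", "manifest.json"))
      for (f in c("full_length.txt", "full_length.txt.json", "reference.txt",
                  "reference.txt.json", "probes.csv", "manifest.json")) {
        add_artifact(file.path("spectra", f))
      }
      inputs$full_length_spectrum <- file.path(out_dir, "spectra", "full_length.txt")
      inputs$reference_spectrum <- file.path(out_dir, "spectra", "reference.txt")
      inputs$probes_csv <- file.path(out_dir, "spectra", "probes.csv")
    })

    stage("simulate-itc", {
      dir.create(file.path(out_dir, "itc"), showWarnings = FALSE)
      files <- character()
      specs <- cfg$itc %||% list()
      for (i in seq_along(specs)) {
        b <- specs[[i]]
        tit <- generate_itc_titration(
          n = b$n %||% 1, Kd = (b$Kd_uM %||% 1) * 1e-6,
          dH = b$dH_kcal %||% 10,
          cell_conc = (b$cell_conc_uM %||% 40) * 1e-6,
          syringe_conc = (b$syringe_conc_mM %||% 0.4) * 1e-3,
          cell_volume = (b$cell_volume_uL %||% 200) * 1e-6,
          injection_volumes = rep((b$injection_volume_uL %||% 1.5) * 1e-6,
                                  b$n_injections %||% 25L),
          heat_noise_sigma = b$heat_noise_ucal %||% 0,
          dilution_heat = b$dilution_heat_ucal %||% 0,
          seed = cfg$seed + 100L + i)
        fname <- sprintf("%s_%s.csv", b$construct %||% sprintf("construct%d", i),
                         b$nucleotide %||% "ATP")
        write_itc_csv(tit, file.path(out_dir, "itc", fname))
        add_artifact(file.path("itc", fname))
        files <- c(files, file.path(out_dir, "itc", fname))
      }
      if (length(files)) inputs$itc_files <- files
    })

    stage("simulate-panel", {
      pn <- cfg$panel %||% list()
      params <- linkage_parameters((pn$Kd_D_nM %||% 1) * 1e-9,
                                   (pn$Kd_U_nM %||% 800) * 1e-9)
      fractions <- unlist(pn$docked_fractions) %||%
        c(0.08, 0.25, 0.45, 0.53, 0.68, 0.85)
      panel <- generate_construct_panel(params, fractions,
                                        scatter_sd = pn$scatter_sd %||% 0,
                                        seed = cfg$seed + 200L,
                                        nucleotide = pn$nucleotide %||% "ATP")
      dir.create(file.path(out_dir, "panel"), showWarnings = FALSE)
      write_panel_csv(panel, file.path(out_dir, "panel", "panel.csv"))
      write_manifest(attr(panel, "truth"),
                     file.path(out_dir, "panel", "manifest.json"))
      add_artifact(file.path("panel", "panel.csv"))
      add_artifact(file.path("panel", "manifest.json"))
      inputs$panel_csv <- file.path(out_dir, "panel", "panel.csv")
    })
  }

  if (cfg$mode %in% c("analyze", "all")) {
    tol <- cfg$tolerances

    if (!is.null(inputs$full_length_spectrum)) {
      results$population <- stage("quantify", {
        fl <- read_spectrum(inputs$full_length_spectrum)
        ref <- read_spectrum(inputs$reference_spectrum)
        probes <- utils::read.csv(inputs$probes_csv, stringsAsFactors = FALSE)
        doublets <- quantify_doublets(fl, ref, probes,
                                      match_tolerance = tol$match_tolerance_ppm,
                                      doublet_window = tol$doublet_window_ppm,
                                      carbon_weight = tol$carbon_weight)
        est <- estimate_populations(doublets,
                                    noise_sigma = estimate_noise(fl))
        bound <- exchange_timescale_bound(doublets$ddH, doublets$ddC,
                                          sfrq_h_MHz = fl$axis_H$sfrq_MHz,
                                          sfrq_c_MHz = fl$axis_C$sfrq_MHz)
        dir.create(file.path(out_dir, "nmr"), showWarnings = FALSE)
        write_population_report(est, file.path(out_dir, "nmr", "population_report.csv"))
        utils::write.csv(as.data.frame(doublets),
                         file.path(out_dir, "nmr", "doublets.csv"),
                         row.names = FALSE, quote = FALSE)
        jsonlite::write_json(
          list(p_D_pct = est$p_D, p_U_pct = est$p_U, error_pct = est$error,
               n_doublets = est$n_doublets,
               exchange_tau_s = bound$tau_s,
               exchange_tau_2pi_s = bound$tau_2pi_s,
               dnu_min_Hz = bound$dnu_min_Hz),
          file.path(out_dir, "nmr", "nmr_summary.json"),
          auto_unbox = TRUE, digits = NA)
        for (f in c("population_report.csv", "doublets.csv", "nmr_summary.json")) {
          add_artifact(file.path("nmr", f))
        }
        est
      })
    }

    if (length(inputs$itc_files %||% character())) {
      results$thermo <- stage("fit-itc", {
        entries <- do.call(rbind, lapply(inputs$itc_files, function(f) {
          tit <- read_itc_csv(f)
          fit <- fit_single_site(tit)
          parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1L]]
          data.frame(construct = paste(utils::head(parts, -1L), collapse = "_"),
                     nucleotide = utils::tail(parts, 1L),
                     Kd_uM = coef(fit)[["Kd"]] * 1e6,
                     dH = coef(fit)[["dH"]],
                     stringsAsFactors = FALSE)
        }))
        tab <- thermo_table(entries)
        dir.create(file.path(out_dir, "itc"), showWarnings = FALSE)
        write_thermo_table(tab, file.path(out_dir, "itc", "thermo_table.csv"), "csv")
        write_thermo_table(tab, file.path(out_dir, "itc", "thermo_table.json"), "json")
        add_artifact(file.path("itc", "thermo_table.csv"))
        add_artifact(file.path("itc", "thermo_table.json"))
        tab
      })
    }

    if (!is.null(inputs$panel_csv)) {
      results$linkage <- stage("link", {
        panel <- read_panel_csv(inputs$panel_csv)
        fit <- fit_state_constants(panel)
        dir.create(file.path(out_dir, "linkage"), showWarnings = FALSE)
        jsonlite::write_json(
          list(Kd_D_M = coef(fit)[["Kd_D"]], Kd_U_M = coef(fit)[["Kd_U"]],
               residuals_RT = fit$residuals, constructs = panel$construct,
               identifiable = fit$identifiable),
          file.path(out_dir, "linkage", "linkage.json"),
          auto_unbox = TRUE, digits = NA)
        curve_df <- theoretical_curve(fit$params)
        utils::write.csv(curve_df, file.path(out_dir, "linkage", "curve.csv"),
                         row.names = FALSE, quote = FALSE)
        add_artifact(file.path("linkage", "linkage.json"))
        add_artifact(file.path("linkage", "curve.csv"))
        fit
      })
    }
  }

  manifest <- list(config_hash = config_hash, seed = cfg$seed,
                   mode = cfg$mode, stages = stages, artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_log(log_con, "pipeline complete: %d stage(s), %d artifact(s)",
          length(stages), length(artifacts))
  invisible(c(list(manifest = manifest), results))
}
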