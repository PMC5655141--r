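# Single-site ITC: exact forward model under the displaced-volume
# ("perfusion") dilution convention, nonlinear least-squares fitting of
# (n, Kd, dH, dilution-heat offset), and the derived state functions
# dG = R T ln Kd and -TdS = dG - dH.

#' Construct an ITC titration object
#'
#' @param cell_conc protein concentration in the cell before titration (M)
#' @param syringe_conc titrant concentration in the syringe (M)
#' @param cell_volume calorimeter cell volume (L)
#' @param temperature temperature (K)
#' @param injections data.frame with columns `volume_L` and `heat_ucal`
#' @return object of class `"itc_titration"`
#' @export
itc_titration <- function(cell_conc, syringe_conc, cell_volume,
                          temperature = 298, injections) {
  stopifnot(is.data.frame(injections),
            all(c("volume_L", "heat_ucal") %in% names(injections)))
  if (cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0) {
    stop_docklink("itc_titration: concentrations and volumes must be positive")
  }
  if (any(injections$volume_L <= 0)) {
    stop_docklink("itc_titration: injection volumes must be positive")
  }
  if (any(!is.finite(injections$heat_ucal))) {
    stop_docklink("itc_titration: heats must be finite")
  }
  structure(
    list(cell_conc = cell_conc, syringe_conc = syringe_conc,
         cell_volume = cell_volume, temperature = temperature,
         injections = injections),
    class = "itc_titration"
  )
}

# cell-contents totals under the displaced-volume convention: after a
# cumulative injected volume dv, active concentrations scale by
# (1 - dv/2V0)/(1 + dv/2V0) for the species originally in the cell, while
# the titrant delivered (syringe_conc * dv / V0) is diluted by
# 1/(1 + dv/2V0)
cell_totals <- function(cell_conc, syringe_conc, cell_volume, injection_volumes) {
  dv <- cumsum(injection_volumes)
  f <- dv / (2 * cell_volume)
  list(
    P = cell_conc * (1 - f) / (1 + f),
    L = syringe_conc * (dv / cell_volume) / (1 + f),
    dv = dv
  )
}

#' Molar ratio (total titrant over total protein) after each injection
#' @param titration an [itc_titration()]
#' @return numeric vector, one value per injection
#' @export
molar_ratio <- function(titration) {
  tot <- cell_totals(titration$cell_conc, titration$syringe_conc,
                     titration$cell_volume, titration$injections$volume_L)
  tot$L / tot$P
}

# exact single-site bound-complex concentration from the quadratic root
# of mass action; numerically negative discriminants are clamped at zero
single_site_complex <- function(n, Kd, P, L) {
  b <- n * P + L + Kd
  disc <- b^2 - 4 * n * P * L
  if (any(disc < 0)) {
    warning("single-site model: negative discriminant clamped to 0",
            call. = FALSE)
    disc <- pmax(disc, 0)
  }
  (b - sqrt(disc)) / 2
}

#' Single-site forward model for injection heats
#'
#' Cumulative heat after injection i is `Q_i = V0 * dH * PL_i` with the
#' bound complex `PL` from the exact quadratic root of single-site mass
#' action; the observed heat of injection i applies the displaced-volume
#' correction `q_i = Q_i - Q_(i-1) + (dV_i/V0) * (Q_i + Q_(i-1)) / 2`.
#'
#' @param n site stoichiometry
#' @param Kd dissociation constant (M); must be positive
#' @param dH binding enthalpy (kcal/mol)
#' @param cell_conc,syringe_conc,cell_volume cell protein (M), syringe
#'   titrant (M) and cell volume (L)
#' @param injection_volumes per-injection volumes (L)
#' @return model heats per injection (ucal)
#' @export
itc_injection_heats <- function(n, Kd, dH, cell_conc, syringe_conc,
                                cell_volume, injection_volumes) {
  if (Kd <= 0) stop_docklink("itc_injection_heats: Kd must be positive")
  tot <- cell_totals(cell_conc, syringe_conc, cell_volume, injection_volumes)
  PL <- single_site_complex(n, Kd, tot$P, tot$L)
  Q <- cell_volume * dH * PL * 1e9     # kcal -> ucal
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (injection_volumes / cell_volume) * (Q + Qprev) / 2
}

#' Derive binding state functions from Kd and dH
#'
#' `dG = R T ln(Kd / 1 M)` against the 1 M standard state and
#' `-TdS = dG - dH`, with `R = 1.987e-3` kcal mol-1 K-1.
#'
#' @param Kd dissociation constant (M)
#' @param dH binding enthalpy (kcal/mol)
#' @param temperature temperature (K)
#' @param n stoichiometry carried through for reporting
#' @return object of class `"binding_thermo"`: `n`, `Kd`, `dG`, `dH`,
#'   `minus_TdS`, `temperature`
#' @export
derive_state_functions <- function(Kd, dH, temperature = 298, n = 1) {
  if (any(Kd <= 0)) stop_docklink("derive_state_functions: Kd must be positive")
  if (temperature <= 0) stop_docklink("derive_state_functions: temperature must be positive")
  dG <- R_KCAL * temperature * log(Kd)
  structure(
    list(n = n, Kd = Kd, dG = dG, dH = dH, minus_TdS = dG - dH,
         temperature = temperature),
    class = "binding_thermo"
  )
}

#' @export
print.binding_thermo <- function(x, digits = 2, ...) {
  cat(sprintf("binding thermodynamics at %g K (n = %.2f):\n",
              x$temperature, x$n))
  cat(sprintf("  Kd    = %.3g M (%.3g uM)\n", x$Kd, x$Kd * 1e6))
  cat(sprintf("  dG    = %.*f kcal/mol\n", digits, x$dG))
  cat(sprintf("  dH    = %.*f kcal/mol\n", digits, x$dH))
  cat(sprintf("  -TdS  = %.*f kcal/mol\n", digits, x$minus_TdS))
  invisible(x)
}

#' Fit the single-site model to an ITC titration
#'
#' Levenberg-Marquardt least squares of (n, Kd, dH, constant dilution-heat
#' offset) against measured injection heats, with Kd handled on the log
#' scale and bounded in \[1e-12, 1e-1\] M. The first injection is excluded
#' by default (standard practice for syringe backlash). Asymptotic standard
#' errors come from the Jacobian at the optimum.
#'
#' @param titration an [itc_titration()]
#' @param exclude_first drop the first injection from the residuals
#'   (default TRUE)
#' @param start optional named list overriding initial values of `n`, `Kd`,
#'   `dH`, `q_dil`
#' @return object of class `"itc_fit"` with coefficients `n`, `Kd` (M),
#'   `dH` (kcal/mol), `q_dil` (ucal), standard errors, residuals, the
#'   c-value diagnostic, and derived state functions (`$thermo`)
#' @export
fit_single_site <- function(titration, exclude_first = TRUE, start = NULL) {
  stopifnot(inherits(titration, "itc_titration"))
  inj <- titration$injections
  keep <- seq_len(nrow(inj))
  if (exclude_first) keep <- keep[-1L]
  if (length(keep) < 5L) {
    stop_docklink("fit_single_site: need at least 5 usable injections")
  }
  q_obs <- inj$heat_ucal
  vols <- inj$volume_L

  model_heats <- function(n, Kd, dH, q_dil) {
    itc_injection_heats(n, Kd, dH, titration$cell_conc,
                        titration$syringe_conc, titration$cell_volume,
                        vols) + q_dil
  }

  # initial guesses: n = 1; offset from the saturated tail; dH from the
  # first retained injection per mole injected; Kd from the cell protein
  # concentration near half-saturation
  tot <- cell_totals(titration$cell_conc, titration$syringe_conc,
                     titration$cell_volume, vols)
  ratio <- tot$L / tot$P
  q0_init <- mean(q_obs[utils::tail(keep, 3L)])
  first <- keep[1L]
  moles_first <- titration$syringe_conc * vols[first]
  dh_init <- (q_obs[first] - q0_init) / (moles_first * 1e9)
  if (!is.finite(dh_init) || dh_init == 0) dh_init <- 1
  kd_init <- tot$P[which.min(abs(ratio - 0.5))] / 10
  kd_init <- min(max(kd_init, 1e-12), 1e-1)
  init <- list(n = 1, Kd = kd_init, dH = dh_init, q_dil = q0_init)
  init[names(start)] <- start

  par0 <- c(n = init$n, logKd = log(init$Kd), dH = init$dH, q_dil = init$q_dil)
  resid_fun <- function(par) {
    q_obs[keep] - model_heats(par[["n"]], exp(par[["logKd"]]),
                              par[["dH"]], par[["q_dil"]])[keep]
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fun,
    lower = c(1e-3, log(1e-12), -Inf, -Inf),
    upper = c(1e3, log(1e-1), Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info %in% c(0L, 5L, 9L)) {
    stop_docklink(sprintf(
      "fit_single_site: no convergence (info = %d, residual norm = %.4g)",
      fit$info, sqrt(fit$deviance)))
  }
  par <- fit$par
  cf <- c(n = par[["n"]], Kd = exp(par[["logKd"]]), dH = par[["dH"]],
          q_dil = par[["q_dil"]])

  # asymptotic covariance on the internal scale, delta-method for Kd
  dof <- length(keep) - length(par)
  sig2 <- if (dof > 0) fit$deviance / dof else NA_real_
  vc <- try(sig2 * solve(fit$hessian / 2), silent = TRUE)
  se <- if (inherits(vc, "try-error")) rep(NA_real_, 4L) else sqrt(pmax(diag(vc), 0))
  names(se) <- names(par)
  se_out <- c(n = se[["n"]], Kd = se[["logKd"]] * cf[["Kd"]],
              dH = se[["dH"]], q_dil = se[["q_dil"]])

  c_value <- cf[["n"]] * titration$cell_conc / cf[["Kd"]]
  if (is.finite(c_value) && (c_value < 1 || c_value > 1000)) {
    warning(sprintf("fit_single_site: c-value %.3g outside [1, 1000]; Kd poorly constrained",
                    c_value), call. = FALSE)
  }
  kd_constrained <- is.finite(se_out[["Kd"]]) &&
    se_out[["Kd"]] < abs(cf[["Kd"]])

  fitted_heats <- model_heats(cf[["n"]], cf[["Kd"]], cf[["dH"]], cf[["q_dil"]])
  structure(
    list(coefficients = cf, se = se_out,
         vcov_internal = if (inherits(vc, "try-error")) NULL else vc,
         fitted = fitted_heats,
         residuals = q_obs - fitted_heats,
         used = keep, molar_ratio = ratio,
         titration = titration,
         c_value = c_value, kd_constrained = kd_constrained,
         deviance = fit$deviance, info = fit$info,
         thermo = derive_state_functions(cf[["Kd"]], cf[["dH"]],
                                         titration$temperature, cf[["n"]])),
    class = "itc_fit"
  )
}

#' @export
coef.itc_fit <- function(object, ...) object$coefficients

#' @export
residuals.itc_fit <- function(object, ...) object$residuals[object$used]

#' @export
fitted.itc_fit <- function(object, ...) object$fitted

#' @export
predict.itc_fit <- function(object, ...) object$fitted

#' @export
print.itc_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("single-site ITC fit\n")
  cat(sprintf("  n     = %.3f +/- %.3f\n", cf[["n"]], x$se[["n"]]))
  cat(sprintf("  Kd    = %.4g +/- %.2g M (%.3g uM)\n",
              cf[["Kd"]], x$se[["Kd"]], cf[["Kd"]] * 1e6))
  cat(sprintf("  dH    = %.3f +/- %.3f kcal/mol\n", cf[["dH"]], x$se[["dH"]]))
  cat(sprintf("  q_dil = %.3f ucal/injection\n", cf[["q_dil"]]))
  cat(sprintf("  c-value = %.3g%s\n", x$c_value,
              if (x$kd_constrained) "" else "  [Kd unconstrained]"))
  cat(sprintf("  dG = %.2f, -TdS = %.2f kcal/mol at %g K\n",
              x$thermo$dG, x$thermo$minus_TdS, x$thermo$temperature))
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  out <- list(coefficients = tab, thermo = object$thermo,
              c_value = object$c_value,
              rms_residual = sqrt(mean(residuals(object)^2)),
              n_used = length(object$used))
  class(out) <- "summary.itc_fit"
  out
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  cat("single-site ITC fit\n\ncoefficients:\n")
  print(x$coefficients)
  cat(sprintf("\nc-value %.3g; RMS residual %.3g ucal over %d injections\n",
              x$c_value, x$rms_residual, x$n_used))
  print(x$thermo)
  invisible(x)
}

#' @export
plot.itc_fit <- function(x, ...) {
  inj <- x$titration$injections
  moles <- x$titration$syringe_conc * inj$volume_L         # mol injected
  ndp <- inj$heat_ucal * 1e-9 / moles                      # ucal -> kcal/mol
  ndp_fit <- x$fitted * 1e-9 / moles
  graphics::plot(x$molar_ratio, ndp, pch = 16,
                 xlab = "molar ratio", ylab = "kcal per mol of injectant",
                 main = "single-site ITC fit", ...)
  graphics::lines(x$molar_ratio, ndp_fit, col = "red3")
  invisible(x)
}

#' Assemble a thermodynamic ledger across constructs
#'
#' Recomputes `dG` and `-TdS` from each row's `Kd` and `dH` at the given
#' temperature. When printed reference values are supplied, rows whose
#' recomputed values disagree beyond 0.1 kcal/mol are flagged
#' `"inconsistent"` rather than forced to match.
#'
#' @param entries data.frame with columns `construct`, `nucleotide`,
#'   `Kd_uM`, `dH` and optionally `dG_printed`, `mTdS_printed`
#' @param temperature temperature (K)
#' @return data.frame of class `"thermo_table"`: `construct`, `ANP`,
#'   `Kd_uM`, `dG`, `dH`, `mTdS` (kcal/mol, full precision) and `flag`
#' @export
thermo_table <- function(entries, temperature = 298) {
  if (nrow(entries) == 0L) {
    out <- data.frame(construct = character(), ANP = character(),
                      Kd_uM = numeric(), dG = numeric(), dH = numeric(),
                      mTdS = numeric(), flag = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("thermo_table", "data.frame")
    return(out)
  }
  key <- paste(entries$construct, entries$nucleotide)
  if (anyDuplicated(key)) {
    stop_docklink("thermo_table: duplicate (construct, nucleotide) keys: ",
                  paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  th <- derive_state_functions(entries$Kd_uM * 1e-6, entries$dH, temperature)
  stopifnot(all(abs(th$minus_TdS - (th$dG - th$dH)) < 1e-12))
  flag <- rep("", nrow(entries))
  if (all(c("dG_printed", "mTdS_printed") %in% names(entries))) {
    bad <- abs(th$dG - entries$dG_printed) > 0.1 |
      abs(th$minus_TdS - entries$mTdS_printed) > 0.1
    flag[bad] <- "inconsistent"
  }
  out <- data.frame(construct = entries$construct, ANP = entries$nucleotide,
                    Kd_uM = entries$Kd_uM, dG = th$dG, dH = entries$dH,
                    mTdS = th$minus_TdS, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("thermo_table", "data.frame")
  out
}

#' Write a thermodynamic ledger to CSV (presentation rounding) or JSON
#' (full precision)
#'
#' @param tab a [thermo_table()]
#' @param path output path
#' @param format `"csv"` or `"json"`
#' @param digits presentation rounding for the CSV energies
#' @return `path`, invisibly
#' @export
write_thermo_table <- function(tab, path, format = c("csv", "json"),
                               digits = 1) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.data.frame(tab), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    pres <- as.data.frame(tab)
    for (col in c("dG", "dH", "mTdS")) {
      pres[[col]] <- sprintf("%.*f", digits, pres[[col]])
    }
    pres$Kd_uM <- sprintf("%.2f", pres$Kd_uM)
    utils::write.csv(pres, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write the ITC CSV dialect
#'
#' Header comment lines `#cell_conc_M=`, `#syringe_conc_M=`,
#' `#cell_volume_L=`, `#temperature_K=` followed by
#' `injection_volume_uL,heat_ucal` rows. The reader tolerates CRLF line
#' endings and interleaved comments.
#'
#' @param path file path
#' @return an [itc_titration()]
#' @export
read_itc_csv <- function(path) {
  lines <- gsub("\r$", "", readLines(path))
  lines <- lines[nzchar(trimws(lines))]
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_key <- function(key) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(hit)) {
      stop_docklink("read_itc_csv: missing required header '#", key, "=' in ", path)
    }
    as.numeric(sub(paste0("^#", key, "="), "", hit[1L]))
  }
  body <- body[!grepl("^injection_volume_uL", body)]
  if (!length(body)) stop_docklink("read_itc_csv: no injection rows in ", path)
  fields <- strsplit(body, ",")
  inj <- data.frame(
    volume_L = as.numeric(vapply(fields, `[[`, character(1L), 1L)) * 1e-6,
    heat_ucal = as.numeric(vapply(fields, `[[`, character(1L), 2L))
  )
  itc_titration(cell_conc = get_key("cell_conc_M"),
                syringe_conc = get_key("syringe_conc_M"),
                cell_volume = get_key("cell_volume_L"),
                temperature = get_key("temperature_K"),
                injections = inj)
}

#' @rdname read_itc_csv
#' @param titration an [itc_titration()]
#' @export
write_itc_csv <- function(titration, path) {
  stopifnot(inherits(titration, "itc_titration"))
  lines <- c(
    paste0("#cell_conc_M=", format_full(titration$cell_conc)),
    paste0("#syringe_conc_M=", format_full(titration$syringe_conc)),
    paste0("#cell_volume_L=", format_full(titration$cell_volume)),
    paste0("#temperature_K=", format_full(titration$temperature)),
    "injection_volume_uL,heat_ucal",
    paste(format_full(titration$injections$volume_L * 1e6),
          format_full(titration$injections$heat_ucal), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}
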