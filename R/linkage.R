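# Two-state thermodynamic linkage between domain docking and nucleotide
# binding. The observed dissociation constant of an ensemble with docked
# fraction p is the population-weighted sum of the pure-state constants,
#   Kd_obs = p * Kd_D + (1 - p) * Kd_U,
# so dG_bind/RT = ln(p Kd_D + (1-p) Kd_U) traces a sigmoid in the docking
# free energy dG_dock/RT = -ln(p/(1-p)). Free energies are handled in RT
# units throughout; kcal/mol conversion happens only at presentation.

#' Pure-state dissociation constants of the two-state linkage model
#'
#' @param Kd_D dissociation constant of the 100%-docked conformation (M)
#' @param Kd_U dissociation constant of the 100%-undocked conformation (M)
#' @return object of class `"linkage_parameters"`
#' @export
linkage_parameters <- function(Kd_D, Kd_U) {
  if (Kd_D <= 0 || Kd_U <= 0) {
    stop_docklink("linkage_parameters: both pure-state constants must be positive")
  }
  structure(list(Kd_D = Kd_D, Kd_U = Kd_U), class = "linkage_parameters")
}

#' Docking free energy from the docked population
#'
#' `dG_dock/RT = -ln(p_D / (1 - p_D))`; negative when docking dominates.
#'
#' @param p_D docked fraction(s), strictly inside (0, 1)
#' @return dimensionless free energy (RT units)
#' @seealso [population_from_docking_energy()] for the exact inverse
#' @export
docking_free_energy <- function(p_D) {
  if (any(p_D <= 0 | p_D >= 1)) {
    stop_docklink("docking_free_energy: p_D must lie strictly in (0, 1); use the fully-undocked/docked flags for boundary states")
  }
  -log(p_D / (1 - p_D))
}

#' @rdname docking_free_energy
#' @param dG_dock_RT docking free energy in RT units
#' @export
population_from_docking_energy <- function(dG_dock_RT) {
  1 / (1 + exp(dG_dock_RT))
}

#' Observed ensemble dissociation constant
#'
#' `Kd_obs = p_D * Kd_D + (1 - p_D) * Kd_U`: the population-weighted sum of
#' the pure-state constants. Bounded between `min(Kd_D, Kd_U)` and
#' `max(Kd_D, Kd_U)` and monotone in `p_D`.
#'
#' @param params a [linkage_parameters()]
#' @param p_D docked fraction(s) in \[0, 1\]
#' @param weight_affinities if TRUE use the alternative
#'   affinity-weighted convention `1/Kd_obs = p/Kd_D + (1-p)/Kd_U`
#'   (sensitivity analysis only; never the default)
#' @return observed dissociation constant(s) (M)
#' @export
ensemble_kd <- function(params, p_D, weight_affinities = FALSE) {
  stopifnot(inherits(params, "linkage_parameters"))
  if (any(p_D < 0 | p_D > 1)) {
    stop_docklink("ensemble_kd: p_D must lie in [0, 1]")
  }
  if (weight_affinities) {
    1 / (p_D / params$Kd_D + (1 - p_D) / params$Kd_U)
  } else {
    p_D * params$Kd_D + (1 - p_D) * params$Kd_U
  }
}

#' Theoretical linkage curve
#'
#' For each docking free energy `x` (RT units), the docked population is
#' `p = 1/(1 + e^x)` and the binding free energy is
#' `y = ln(ensemble_kd(p))`. The curve runs from `ln Kd_D` (x -> -Inf) to
#' `ln Kd_U` (x -> +Inf).
#'
#' @param params a [linkage_parameters()]
#' @param dg_dock_grid docking free energies (RT units)
#' @param weight_affinities see [ensemble_kd()]
#' @return data.frame with columns `dG_dock_RT`, `p_D`, `dG_bind_RT`
#' @export
theoretical_curve <- function(params, dg_dock_grid = seq(-8, 8, by = 0.05),
                              weight_affinities = FALSE) {
  stopifnot(all(is.finite(dg_dock_grid)))
  p <- population_from_docking_energy(dg_dock_grid)
  data.frame(dG_dock_RT = dg_dock_grid, p_D = p,
             dG_bind_RT = log(ensemble_kd(params, p, weight_affinities)))
}

#' Fit the pure-state constants to a construct panel
#'
#' Least squares in log-Kd space (positivity and scale invariance):
#' minimises `sum(ln Kd_obs - ln(p Kd_D + (1-p) Kd_U))^2` over
#' `(ln Kd_D, ln Kd_U)`. Fully-undocked states enter with `p_D = 0` —
#' the binding equation, unlike the docking free energy, is defined there.
#'
#' @param panel data.frame with columns `p_D` (docked fraction; NA for rows
#'   flagged by a logical `undocked` column, which enter as `p_D = 0`) and
#'   `Kd_M` (observed dissociation constant, M); typically a
#'   `"construct_panel"` from [generate_construct_panel()] or
#'   [read_panel_csv()]
#' @param weight_affinities see [ensemble_kd()]
#' @return object of class `"linkage_fit"` with coefficients `Kd_D`, `Kd_U`
#'   (M), per-construct residuals (RT units), and an identifiability note
#'   when the docked-fraction spread is below 0.2
#' @export
fit_state_constants <- function(panel, weight_affinities = FALSE) {
  panel <- as.data.frame(panel)
  stopifnot(all(c("p_D", "Kd_M") %in% names(panel)))
  p <- panel$p_D
  if ("undocked" %in% names(panel)) p[panel$undocked] <- 0
  if (any(is.na(p))) {
    stop_docklink("fit_state_constants: rows with missing p_D must carry the undocked flag")
  }
  if (any(p < 0 | p > 1)) stop_docklink("fit_state_constants: p_D outside [0, 1]")
  if (any(panel$Kd_M <= 0)) stop_docklink("fit_state_constants: observed Kd must be positive")
  if (length(unique(p)) < 2L) {
    stop_docklink("fit_state_constants: all states share one docked fraction; Kd_D and Kd_U are not separately identifiable")
  }
  spread <- diff(range(p))
  identifiable <- spread >= 0.2
  if (!identifiable) {
    warning(sprintf("fit_state_constants: docked-fraction spread %.2f < 0.2; constants weakly identified",
                    spread), call. = FALSE)
  }
  y <- log(panel$Kd_M)
  model_y <- function(lkD, lkU) {
    pars <- linkage_parameters(exp(lkD), exp(lkU))
    log(ensemble_kd(pars, p, weight_affinities))
  }
  # start at the observed constants nearest the pure states
  start <- c(lkD = y[which.max(p)], lkU = y[which.min(p)])
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(par) y - model_y(par[["lkD"]], par[["lkU"]]),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info %in% c(0L, 5L, 9L)) {
    stop_docklink(sprintf("fit_state_constants: no convergence (info = %d, residual norm = %.4g)",
                          fit$info, sqrt(fit$deviance)))
  }
  cf <- c(Kd_D = exp(fit$par[["lkD"]]), Kd_U = exp(fit$par[["lkU"]]))
  dof <- length(y) - 2L
  sig2 <- if (dof > 0) fit$deviance / dof else NA_real_
  vc <- try(sig2 * solve(fit$hessian / 2), silent = TRUE)
  se_log <- if (inherits(vc, "try-error")) c(NA_real_, NA_real_) else sqrt(pmax(diag(vc), 0))
  res <- y - model_y(fit$par[["lkD"]], fit$par[["lkU"]])
  structure(
    list(coefficients = cf, se_log = se_log,
         params = linkage_parameters(cf[["Kd_D"]], cf[["Kd_U"]]),
         residuals = res, panel = panel, p_used = p,
         identifiable = identifiable, spread = spread,
         weight_affinities = weight_affinities,
         deviance = fit$deviance, info = fit$info),
    class = "linkage_fit"
  )
}

#' @export
coef.linkage_fit <- function(object, ...) object$coefficients

#' @export
residuals.linkage_fit <- function(object, ...) object$residuals

#' @export
print.linkage_fit <- function(x, ...) {
  cat("two-state linkage fit (log-Kd least squares)\n")
  cat(sprintf("  Kd_D = %.4g M (%.3g nM)\n",
              x$coefficients[["Kd_D"]], x$coefficients[["Kd_D"]] * 1e9))
  cat(sprintf("  Kd_U = %.4g M (%.3g nM)\n",
              x$coefficients[["Kd_U"]], x$coefficients[["Kd_U"]] * 1e9))
  cat(sprintf("  %d states, docked-fraction spread %.2f%s\n",
              nrow(x$panel), x$spread,
              if (x$identifiable) "" else "  [weakly identified]"))
  cat(sprintf("  RMS residual %.3g (RT units of dG_bind)\n",
              sqrt(mean(x$residuals^2))))
  if (x$weight_affinities) {
    cat("  note: affinity-weighted (1/Kd) convention in use\n")
  }
  invisible(x)
}

#' @export
summary.linkage_fit <- function(object, ...) {
  out <- list(
    coefficients = cbind(Estimate = object$coefficients,
                         `log-scale SE` = object$se_log),
    residuals = data.frame(construct = object$panel$construct %||%
                             seq_along(object$residuals),
                           p_D = object$p_used,
                           residual_RT = object$residuals),
    identifiable = object$identifiable, spread = object$spread
  )
  class(out) <- "summary.linkage_fit"
  out
}

#' @export
print.summary.linkage_fit <- function(x, ...) {
  cat("two-state linkage fit\n\ncoefficients:\n")
  print(x$coefficients)
  cat("\nper-construct residuals (RT units):\n")
  print(x$residuals, row.names = FALSE)
  cat(sprintf("\ndocked-fraction spread %.2f (%s)\n", x$spread,
              if (x$identifiable) "identifiable" else "weakly identified"))
  invisible(x)
}

#' @export
predict.linkage_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$p_used else newdata$p_D
  ensemble_kd(object$params, p, object$weight_affinities)
}

#' @export
plot.linkage_fit <- function(x, ...) {
  curve_df <- theoretical_curve(x$params,
                                weight_affinities = x$weight_affinities)
  pts_p <- pmin(pmax(x$p_used, 1e-4), 1 - 1e-4)  # boundary states drawn at the asymptote
  pts_x <- docking_free_energy(pts_p)
  pts_y <- log(x$panel$Kd_M)
  graphics::plot(curve_df$dG_dock_RT, curve_df$dG_bind_RT, type = "l",
                 col = "red3", xlab = "dG(docking)/RT",
                 ylab = "dG(binding)/RT = ln Kd",
                 main = "two-state thermodynamic linkage", ...)
  graphics::points(pts_x, pts_y, pch = 16)
  invisible(x)
}

#' Read / write a construct panel CSV
#'
#' Columns `construct`, `nucleotide`, `p_D_percent` (a number, or the word
#' `undocked` for states with no detectable docked peaks) and `Kd_uM`.
#'
#' @param path file path
#' @return data.frame of class `"construct_panel"` with columns
#'   `construct`, `nucleotide`, `p_D` (fraction; NA when undocked),
#'   `undocked` (logical), `Kd_M`
#' @export
read_panel_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("construct", "nucleotide", "p_D_percent", "Kd_uM")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_docklink("read_panel_csv: missing column(s) ",
                  paste(missing_cols, collapse = ", "))
  }
  undocked <- tolower(trimws(raw$p_D_percent)) == "undocked"
  p <- suppressWarnings(as.numeric(raw$p_D_percent)) / 100
  p[undocked] <- NA_real_
  if (any(is.na(p) & !undocked)) {
    stop_docklink("read_panel_csv: p_D_percent must be numeric or 'undocked'")
  }
  out <- data.frame(construct = raw$construct, nucleotide = raw$nucleotide,
                    p_D = p, undocked = undocked,
                    Kd_M = as.numeric(raw$Kd_uM) * 1e-6,
                    stringsAsFactors = FALSE)
  class(out) <- c("construct_panel", "data.frame")
  out
}

#' @rdname read_panel_csv
#' @param panel a construct-panel data.frame (columns `construct`,
#'   `nucleotide`, `p_D`, optionally `undocked`, `Kd_M`)
#' @export
write_panel_csv <- function(panel, path) {
  panel <- as.data.frame(panel)
  undocked <- if ("undocked" %in% names(panel)) panel$undocked else
    rep(FALSE, nrow(panel))
  p_col <- ifelse(undocked, "undocked", format_full(panel$p_D * 100))
  out <- data.frame(construct = panel$construct,
                    nucleotide = panel$nucleotide,
                    p_D_percent = p_col,
                    Kd_uM = format_full(panel$Kd_M * 1e6),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
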