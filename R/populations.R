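# Docked-population estimation from doublet intensities:
# p_D = I_D / (I_D + I_U) * 100 per doublet; the report carries the mean
# across doublets with an error set to the larger of the across-doublet SD
# and the error propagated from per-peak intensity uncertainty.

#' Estimate docked/undocked populations from peak doublets
#'
#' Per doublet, `p_D = I_D / (I_D + I_U) * 100`. The reported population is
#' the mean over usable doublets. The reported error is
#' `max(SD across doublets, propagated intensity error)`: the propagated
#' term carries the per-peak intensity uncertainty `noise_sigma` through the
#' intensity ratio by first-order propagation,
#' `sd(p) = sigma * sqrt(I_D^2 + I_U^2) / (I_D + I_U)^2`, and is summarised
#' across doublets as the root-mean-square per-doublet error (deliberately
#' not divided by `sqrt(n)`; see the methods vignette).
#'
#' @param doublets a `"peak_doublets"` data.frame from [pair_doublets()], or
#'   any data.frame with columns `probe`, `I_D`, `I_U` (and optionally
#'   `status`)
#' @param noise_sigma per-peak intensity standard deviation (amplitude
#'   units); 0 drops the propagated term
#' @param include_overlapped include doublets flagged `"overlapped"`
#'   (default FALSE)
#' @return object of class `"population_estimate"`: `p_D`, `p_U`, `error`
#'   (all percent), `per_doublet` table, `n_doublets`, `sd_pct`,
#'   `propagated_pct`
#' @export
estimate_populations <- function(doublets, noise_sigma = 0,
                                 include_overlapped = FALSE) {
  d <- as.data.frame(doublets)
  if ("status" %in% names(d)) {
    keep <- d$status == "doublet" | (include_overlapped & d$status == "overlapped")
    d <- d[keep, , drop = FALSE]
  }
  d <- d[!is.na(d$I_D) & !is.na(d$I_U), , drop = FALSE]
  if (nrow(d) == 0L) {
    stop_docklink("estimate_populations: no doublets to estimate from")
  }
  neg <- d$I_D < 0 | d$I_U < 0
  if (any(neg)) {
    warning("estimate_populations: negative intensities clamped to 0",
            call. = FALSE)
    d$I_D <- pmax(d$I_D, 0)
    d$I_U <- pmax(d$I_U, 0)
  }
  s <- d$I_D + d$I_U
  if (any(s <= 0)) {
    stop_docklink("estimate_populations: doublet with non-positive total intensity")
  }
  p <- d$I_D / s * 100
  sd_pct <- if (length(p) > 1L) stats::sd(p) else 0
  prop_each <- noise_sigma * sqrt(d$I_D^2 + d$I_U^2) / s^2 * 100
  propagated_pct <- sqrt(mean(prop_each^2))
  err <- max(sd_pct, propagated_pct)
  structure(
    list(p_D = mean(p), p_U = 100 - mean(p), error = err,
         per_doublet = data.frame(probe = d$probe, I_U = d$I_U, I_D = d$I_D,
                                  p_D = p, stringsAsFactors = FALSE),
         n_doublets = nrow(d), sd_pct = sd_pct,
         propagated_pct = propagated_pct, noise_sigma = noise_sigma),
    class = "population_estimate"
  )
}

#' @export
print.population_estimate <- function(x, digits = 1, ...) {
  cat(sprintf("docked population: p_D = %.*f +/- %.*f %% (p_U = %.*f %%)\n",
              digits, x$p_D, digits, x$error, digits, x$p_U))
  cat(sprintf("  %d doublet(s); SD = %.2f %%, propagated = %.2f %% (max taken)\n",
              x$n_doublets, x$sd_pct, x$propagated_pct))
  invisible(x)
}

#' Write a population report as CSV
#'
#' One row per doublet (`probe`, `I_U`, `I_D`, `p_D_pct`) followed by a
#' `summary` row holding the mean and its error.
#'
#' @param est a [estimate_populations()] result
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_population_report <- function(est, path) {
  stopifnot(inherits(est, "population_estimate"))
  per <- est$per_doublet
  tab <- data.frame(probe = c(per$probe, "summary"),
                    I_U = c(format_full(per$I_U), ""),
                    I_D = c(format_full(per$I_D), ""),
                    p_D_pct = format_full(c(per$p_D, est$p_D)),
                    error_pct = c(rep("", nrow(per)), format_full(est$error)),
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
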