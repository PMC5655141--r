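# Shared physical constants and small internal helpers.

#' Ideal gas constant in kcal mol-1 K-1
#'
#' Value used throughout for free-energy arithmetic (`dG = R T ln Kd`).
#' @export
R_KCAL <- 1.987e-3

# gyromagnetic ratio of 13C relative to 1H; converts a 1H spectrometer
# frequency to the 13C axis frequency (e.g. 750 MHz -> 188.6 MHz)
GAMMA_13C_OVER_1H <- 0.251449530

#' Carbon axis frequency for a given proton frequency
#'
#' @param sfrq_h_MHz proton spectrometer frequency in MHz
#' @return the 13C Larmor frequency in MHz
#' @export
carbon_frequency <- function(sfrq_h_MHz) sfrq_h_MHz * GAMMA_13C_OVER_1H

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_docklink <- function(...) stop(..., call. = FALSE)

# full-precision numeric formatting for text artefacts that must
# round-trip bit-exactly through read/write
format_full <- function(x) sprintf("%.17g", x)
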