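#' Evaluation options for the equation compendium
#'
#' Several printed formulas in the source compendium contain transcription
#' quirks (a truncated constant, a coefficient off by a power of ten, a
#' missing standardisation step). By default the package evaluates each
#' equation in the physically coherent reading that reproduces published
#' cohort-level values; `as_printed = TRUE` switches the affected equations
#' to their literal printed arithmetic (documented per equation in the
#' methods vignette), which can produce non-physical masses.
#'
#' @param as_printed logical; evaluate literal printed forms of the
#'   ISAK/Kerr fat-mass, Poortmans and Doupe equations. Default `FALSE`.
#' @param full_pi logical; use machine `pi` instead of the printed 3.141
#'   inside corrected girths. Default `FALSE` (reproduce printed arithmetic).
#' @param heymsfield_coefficient height coefficient of the Heymsfield
#'   lean-mass equation. The compendium prints 0.284 (the default); the
#'   widely published value is 0.0264.
#' @param oconnor_squared logical; use the quadratic second term
#'   `0.0005 * S^2` in the O'Connor equation instead of the printed linear
#'   pair (which collapses to a single coefficient). Default `FALSE`.
#' @param kerr_adipose_c1,kerr_adipose_c2 centring and scaling constants of
#'   the adipose Z-score in the ISAK/Kerr five-way fractionation
#'   (`Z = (sum6SK * 170.18/H - c1)/c2`). Defaults 116.41 and 34.79.
#'
#' @return A named list of class `anthro_options`.
#' @export
#' @examples
#' anthro_options()
#' anthro_options(full_pi = TRUE)
anthro_options <- function(as_printed = FALSE,
                           full_pi = FALSE,
                           heymsfield_coefficient = 0.284,
                           oconnor_squared = FALSE,
                           kerr_adipose_c1 = 116.41,
                           kerr_adipose_c2 = 34.79) {
  stopifnot(is.logical(as_printed), is.logical(full_pi),
            is.numeric(heymsfield_coefficient),
            is.numeric(kerr_adipose_c1), is.numeric(kerr_adipose_c2))
  structure(list(as_printed = as_printed,
                 full_pi = full_pi,
                 heymsfield_coefficient = heymsfield_coefficient,
                 oconnor_squared = oconnor_squared,
                 kerr_adipose_c1 = kerr_adipose_c1,
                 kerr_adipose_c2 = kerr_adipose_c2),
            class = "anthro_options")
}

.pi_factor <- function(opts) if (isTRUE(opts$full_pi)) pi else 3.141
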