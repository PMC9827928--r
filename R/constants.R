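#' Model constants for the C4 leakiness calculation
#'
#' Returns the set of biochemical and isotopic constants used throughout the
#' leakiness calculation. Every value can be overridden; the defaults are the
#' standard literature values for NADP-ME species (maize, sorghum) measured at
#' 27 degrees C.
#'
#' All CO2 and O2 quantities are mole fractions in umol mol-1 of dry air;
#' fractionation factors are in permil.
#'
#' @param a Fractionation across the stomata (permil). Default 4.4.
#' @param ab Fractionation across the boundary layer (permil). Default 2.9.
#' @param b3_prime 13C fractionation by Rubisco carboxylation (permil).
#'   Default 30.
#' @param s Fractionation during leakage out of the bundle sheath (permil).
#'   Default 1.8.
#' @param f Fractionation during photorespiration (permil). Default 11.6.
#' @param e Respiratory fractionation during decarboxylation (permil).
#'   Default 0.
#' @param gbs Bundle-sheath conductance to CO2 (mol m-2 s-1). Default 0.00113.
#' @param x Fraction of total electron transport (ATP) allocated to the C4
#'   cycle. Default 0.4.
#' @param alpha Fraction of PSII activity in the bundle sheath. Default 0.
#' @param gamma_star Half the reciprocal of Rubisco specificity
#'   (dimensionless). Default 0.000193.
#' @param Om Mesophyll O2 mole fraction (umol mol-1). Default 210000.
#' @param delta_gatm delta-13C of the growth-environment CO2 (permil).
#'   Default -8.
#' @param rm_fraction Mesophyll fraction of day respiration: Rm =
#'   rm_fraction * Rd. Default 0.5.
#' @param r_standard 13C/12C isotope ratio of the VPDB standard. Default
#'   0.0111797.
#' @param ternary_permil_literal Logical; if `TRUE` the combined diffusional
#'   fractionation enters the ternary factor as its raw permil value rather
#'   than as a fraction (sensitivity switch, see [ternary_t()]).
#' @param error_model Either `"2xiX"` (the printed instrument-error form) or
#'   `"sqrt2xiX"` (sensitivity alternative), see [discrimination_error()].
#'
#' @return A named list with class `"c4_constants"`.
#' @export
#' @examples
#' cst <- c4_constants()
#' cst$gbs
#' c4_constants(f = 1.6)$f  # override
c4_constants <- function(a = 4.4, ab = 2.9, b3_prime = 30, s = 1.8,
                         f = 11.6, e = 0, gbs = 0.00113, x = 0.4,
                         alpha = 0, gamma_star = 0.000193, Om = 210000,
                         delta_gatm = -8, rm_fraction = 0.5,
                         r_standard = 0.0111797,
                         ternary_permil_literal = FALSE,
                         error_model = c("2xiX", "sqrt2xiX")) {
  stopifnot(x >= 0, x <= 1, alpha >= 0, alpha <= 1, gbs > 0,
            gamma_star > 0, Om > 0, r_standard > 0)
  cst <- list(a = a, ab = ab, b3_prime = b3_prime, s = s, f = f, e = e,
              gbs = gbs, x = x, alpha = alpha, gamma_star = gamma_star,
              Om = Om, delta_gatm = delta_gatm, rm_fraction = rm_fraction,
              r_standard = r_standard,
              ternary_permil_literal = isTRUE(ternary_permil_literal),
              error_model = match.arg(error_model))
  class(cst) <- "c4_constants"
  cst
}

#' @export
print.c4_constants <- function(x, ...) {
  cat("C4 leakiness model constants:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Merge user overrides (possibly a partial list from a config file) into the
# default constant set, keeping unknown keys out.
as_c4_constants <- function(x) {
  if (inherits(x, "c4_constants")) return(x)
  if (is.null(x)) return(c4_constants())
  stopifnot(is.list(x))
  known <- names(formals(c4_constants))
  do.call(c4_constants, x[intersect(names(x), known)])
}
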