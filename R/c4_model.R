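#' Total electron transport rate from net assimilation
#'
#' Inverts the von Caemmerer light-limited C4 model for the total electron
#' transport rate Jt (umol m-2 s-1) at a measured net assimilation A. Jt is
#' a root of the quadratic `III * Jt^2 + II * Jt + I = 0` obtained from the
#' mesophyll CO2 mass balance `gbs * (Cbs - Cm) = x*Jt/2 - A - Rm` after
#' substituting the bundle-sheath relations (see [bundle_sheath_state()]),
#' with `Rm = rm_fraction * Rd` and mesophyll CO2 `Cm` taken equal to
#' measured Ci:
#' \preformatted{
#'   III = x (1 - x) / 6
#'   II  = -x (A + Rd) / 2
#'         - (1 - x)/3 * (A + Rm - gbs Cm + gbs gamma_star Os)
#'   I   = (A + Rd) * (A + Rm - gbs Cm - 7/3 gbs gamma_star Os)
#' }
#' with `Os = alpha * A / (0.047 gbs) + Om`. Both roots are computed; a root
#' is admissible if it is real, positive and satisfies
#' `(1 - x) Jt / 3 > A + Rd` (positive bundle-sheath denominator). If both
#' roots are admissible the one giving the smaller Cbs (the larger root) is
#' taken, with a warning.
#'
#' @param A Net CO2 assimilation (umol m-2 s-1); `A + Rd` must be positive.
#' @param Rd Day respiration (umol m-2 s-1).
#' @param Cm Mesophyll CO2 mole fraction (umol mol-1), taken = Ci.
#' @param constants A [c4_constants()] set.
#' @param strict If `TRUE`, a negative discriminant raises an error carrying
#'   the discriminant; otherwise such points become `NA`.
#' @return Jt (umol m-2 s-1), `NA` where no admissible root exists.
#' @export
electron_transport <- function(A, Rd, Cm, constants = c4_constants(),
                               strict = FALSE) {
  cst <- constants
  n <- max(length(A), length(Rd), length(Cm))
  A <- rep_len(A, n); Rd <- rep_len(Rd, n); Cm <- rep_len(Cm, n)
  Rm <- cst$rm_fraction * Rd
  Os <- cst$alpha * A / (0.047 * cst$gbs) + cst$Om
  S <- A + Rd
  gO <- cst$gbs * cst$gamma_star * Os
  qIII <- cst$x * (1 - cst$x) / 6
  qII <- -cst$x * S / 2 - (1 - cst$x) / 3 * (A + Rm - cst$gbs * Cm + gO)
  qI <- S * (A + Rm - cst$gbs * Cm - 7 / 3 * gO)
  disc <- qII^2 - 4 * qIII * qI
  if (strict && any(!is.na(disc) & disc < 0))
    stop("no real electron-transport root; discriminant = ",
         paste(signif(disc[!is.na(disc) & disc < 0], 6), collapse = ", "))
  sq <- sqrt(pmax(disc, 0))
  r1 <- (-qII + sq) / (2 * qIII)
  r2 <- (-qII - sq) / (2 * qIII)
  admissible <- function(r) !is.na(r) & disc >= 0 & r > 0 &
    (1 - cst$x) * r / 3 > S & S > 0
  a1 <- admissible(r1)
  a2 <- admissible(r2)
  if (any(a1 & a2))
    warning(sum(a1 & a2), " point(s) with two admissible roots; ",
            "taking the one with smaller bundle-sheath CO2")
  out <- ifelse(a1, r1, ifelse(a2, r2, NA_real_))
  out
}

#' Bundle-sheath state at a given electron transport rate
#'
#' Computes the bundle-sheath O2 and CO2 mole fractions and the component
#' fluxes of the von Caemmerer light-limited C4 model:
#' \preformatted{
#'   Os  = alpha A / (0.047 gbs) + Om
#'   Cbs = gamma_star Os (7/3 (A + Rd) + (1 - x) Jt / 3) /
#'         ((1 - x) Jt / 3 - (A + Rd))
#'   Vp  = x Jt / 2
#'   Vc  = (A + Rd) / (1 - gamma_star Os / Cbs)
#'   Vo  = (Vc - A - Rd) / 0.5
#' }
#' The identity `A = Vc - 0.5 Vo - Rd` holds by construction. Points where
#' `(1 - x) Jt / 3 <= A + Rd` (inadmissible root or bad inputs) are `NA`.
#'
#' @param A,Rd As in [electron_transport()].
#' @param Jt Total electron transport rate (umol m-2 s-1).
#' @param constants A [c4_constants()] set.
#' @return Data frame with `Jt`, `Os`, `Cbs`, `Vp`, `Vc`, `Vo`.
#' @export
bundle_sheath_state <- function(A, Rd, Jt, constants = c4_constants()) {
  cst <- constants
  n <- max(length(A), length(Rd), length(Jt))
  A <- rep_len(A, n); Rd <- rep_len(Rd, n); Jt <- rep_len(Jt, n)
  S <- A + Rd
  Os <- cst$alpha * A / (0.047 * cst$gbs) + cst$Om
  J3 <- (1 - cst$x) * Jt / 3
  ok <- !is.na(Jt) & J3 > S
  Cbs <- ifelse(ok, cst$gamma_star * Os * (7 / 3 * S + J3) / (J3 - S),
                NA_real_)
  Vp <- ifelse(ok, cst$x * Jt / 2, NA_real_)
  Vc <- ifelse(ok, S / (1 - cst$gamma_star * Os / Cbs), NA_real_)
  Vo <- (Vc - S) / 0.5
  data.frame(Jt = ifelse(ok, Jt, NA_real_), Os = Os, Cbs = Cbs,
             Vp = Vp, Vc = Vc, Vo = Vo)
}

#' Combined diffusional fractionation across boundary layer and stomata
#'
#' `a' = (ab (Ca - Cs) + a (Cs - Ci)) / (Ca - Ci)` permil: the weighted mean
#' of the boundary-layer (2.9 permil) and stomatal (4.4 permil)
#' fractionations, weighted by the CO2 drawdown across each resistance.
#'
#' @param Ca,Cs,Ci Ambient, leaf-surface and intercellular CO2 (umol mol-1).
#' @param constants A [c4_constants()] set.
#' @return a' in permil; `NA` where Ca = Ci.
#' @export
combined_a_prime <- function(Ca, Cs, Ci, constants = c4_constants()) {
  ifelse(Ca == Ci, NA_real_,
         (constants$ab * (Ca - Cs) + constants$a * (Cs - Ci)) / (Ca - Ci))
}

#' Ternary correction factor
#'
#' `t = (1 + a') E / (2 gact)`, the correction for the interaction of the
#' transpiration flux with CO2 diffusion. The combined fractionation a'
#' enters as a fraction (permil / 1000), following the Farquhar--Cernusak
#' ternary formulation; set `c4_constants(ternary_permil_literal = TRUE)` to
#' use the raw permil value instead (sensitivity check).
#'
#' @param a_prime Combined diffusional fractionation (permil).
#' @param E Transpiration rate (mol m-2 s-1).
#' @param gact Total conductance to CO2, boundary layer plus stomata
#'   (mol m-2 s-1); must be positive.
#' @param constants A [c4_constants()] set.
#' @return t (dimensionless); `NA` where gact <= 0.
#' @export
#' @examples
#' ternary_t(4.4, 0.004, 0.4)  # 0.005022
ternary_t <- function(a_prime, E, gact, constants = c4_constants()) {
  ap <- if (constants$ternary_permil_literal) a_prime else a_prime / 1000
  ifelse(gact > 0, (1 + ap) * E / (2 * gact), NA_real_)
}

#' Temperature-dependent PEPC fractionation
#'
#' `b4' = -9.483 * 1000 / (273 + T) + 23.89 + 2.2` permil: the net
#' fractionation by CO2 dissolution, hydration and PEP carboxylation at leaf
#' temperature T (degrees C).
#'
#' @param Tleaf_C Leaf temperature in degrees C (plausible range 0--50).
#' @return b4' in permil.
#' @export
#' @examples
#' b4_prime(27)  # -5.52 permil
b4_prime <- function(Tleaf_C) {
  if (any(Tleaf_C < 0 | Tleaf_C > 50, na.rm = TRUE))
    warning("leaf temperature outside the physically plausible 0-50 C range")
  -9.483 * 1000 / (273 + Tleaf_C) + 23.89 + 2.2
}

#' Apparent respiratory fractionation
#'
#' `e' = e + delta13C_ref - delta13C_gatm` permil: the decarboxylation
#' fractionation including the offset between the measurement CO2 and the
#' growth-environment CO2 feeding the respiratory substrate.
#'
#' @param delta_ref delta-13C of the reference (measurement) CO2, permil.
#'   Values outside (-10, -6.5) permil trigger a warning.
#' @param constants A [c4_constants()] set.
#' @return e' in permil.
#' @export
e_prime <- function(delta_ref, constants = c4_constants()) {
  if (any(delta_ref < -10 | delta_ref > -6.5, na.rm = TRUE))
    warning("delta13C_ref outside the expected (-10, -6.5) permil range")
  constants$e + delta_ref - constants$delta_gatm
}

#' Effective carboxylation fractionations b3 and b4
#'
#' `b3 = b3' - e' Rd / Vc - f Vo / Vc` folds respiratory and
#' photorespiratory fractionation into the Rubisco term;
#' `b4 = b4'(T) - e' Rm / Vp` folds mesophyll respiration into the PEPC
#' term, with `Rm = rm_fraction * Rd`.
#'
#' @param state [bundle_sheath_state()] result (needs `Vc`, `Vo`, `Vp`).
#' @param e_prime Apparent respiratory fractionation (permil).
#' @param Rd Day respiration (umol m-2 s-1).
#' @param Tleaf_C Leaf temperature (degrees C) for b4'.
#' @param constants A [c4_constants()] set.
#' @return Data frame with `b3` and `b4` (permil); `NA` where Vc or Vp <= 0.
#' @export
b3_b4 <- function(state, e_prime, Rd, Tleaf_C, constants = c4_constants()) {
  cst <- constants
  ok <- !is.na(state$Vc) & state$Vc > 0 & state$Vp > 0
  b3 <- ifelse(ok, cst$b3_prime - e_prime * Rd / state$Vc -
                 cst$f * state$Vo / state$Vc, NA_real_)
  b4 <- ifelse(ok, b4_prime(Tleaf_C) -
                 e_prime * cst$rm_fraction * Rd / state$Vp, NA_real_)
  data.frame(b3 = b3, b4 = b4)
}

#' Bundle-sheath leakiness from observed discrimination
#'
#' Inverts the complete discrimination model (infinite mesophyll
#' conductance, Cm = Ci) for leakiness:
#' \preformatted{
#'   phi = (Cbs - Ci)/Ci *
#'         ((1 - t) Delta Ca - a'(Ca - Ci) - (1 + t) Ci b4) /
#'         ((1 + t)(b3 Cbs - s (Cbs - Ci)) + a'(Ca - Ci) - (1 - t) Delta Ca)
#' }
#' Points with a near-zero denominator are `NA`; estimates outside
#' [-0.5, 1.5] are physically implausible and flagged (attribute
#' `implausible`), never clipped.
#'
#' @param delta_obs Observed discrimination Delta13C_obs (permil).
#' @param Ca,Ci Ambient and intercellular CO2 (umol mol-1).
#' @param Cbs Bundle-sheath CO2 (umol mol-1), from [bundle_sheath_state()].
#' @param tern Ternary factor t, from [ternary_t()].
#' @param a_prime Combined diffusional fractionation (permil).
#' @param b3,b4 Effective fractionations (permil), from [b3_b4()].
#' @param constants A [c4_constants()] set.
#' @return phi (dimensionless) with logical attribute `implausible`.
#' @export
leakiness <- function(delta_obs, Ca, Ci, Cbs, tern, a_prime, b3, b4,
                      constants = c4_constants()) {
  s <- constants$s
  z <- (1 - tern) * delta_obs * Ca
  num <- z - a_prime * (Ca - Ci) - (1 + tern) * Ci * b4
  den <- (1 + tern) * (b3 * Cbs - s * (Cbs - Ci)) +
    a_prime * (Ca - Ci) - z
  phi <- ifelse(!is.na(den) & abs(den) > sqrt(.Machine$double.eps),
                (Cbs - Ci) / Ci * num / den, NA_real_)
  attr(phi, "implausible") <- !is.na(phi) & (phi < -0.5 | phi > 1.5)
  phi
}

#' Forward discrimination at a prescribed leakiness
#'
#' The exact inverse of [leakiness()]: the unique Delta13C_obs that the
#' complete discrimination model predicts for a given phi and leaf state.
#' Because the leakiness expression is a ratio of terms affine in Delta, the
#' solution is closed form.
#'
#' @inheritParams leakiness
#' @param phi Leakiness (dimensionless).
#' @return Delta13C_obs in permil.
#' @export
forward_discrimination <- function(phi, Ca, Ci, Cbs, tern, a_prime, b3, b4,
                                   constants = c4_constants()) {
  s <- constants$s
  K <- (Cbs - Ci) / Ci
  P <- (1 + tern) * (b3 * Cbs - s * (Cbs - Ci))
  G <- a_prime * (Ca - Ci)
  B <- (1 + tern) * Ci * b4
  den <- (K + phi) * (1 - tern) * Ca
  ifelse(!is.na(den) & abs(den) > sqrt(.Machine$double.eps),
         (phi * (P + G) + K * (G + B)) / den, NA_real_)
}

#' ATP cost of net CO2 assimilation at a given leakiness
#'
#' C4 photosynthesis spends 3 ATP per carboxylation in the C3 cycle plus
#' 2 ATP per PEP regeneration; CO2 that leaks back out of the bundle sheath
#' must be re-pumped, inflating the C4-cycle term by the overcycling factor
#' `1 / (1 - phi)`:
#' `ATP per net CO2 = 3 + 2 / (1 - phi)`.
#'
#' @param phi Leakiness in [0, 1).
#' @return ATP consumed per net CO2 assimilated.
#' @export
#' @examples
#' atp_cost(0.2)   # 5.5
#' atp_cost(0.25)  # 5.667 -> 5.7 at one decimal
atp_cost <- function(phi) {
  if (any(phi < 0 | phi >= 1))
    stop("phi must lie in [0, 1): full leakage has unbounded cost")
  3 + 2 / (1 - phi)
}
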