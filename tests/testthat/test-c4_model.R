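# Independent oracle: the printed (divided-by-A) quadratic coefficients.
quad_coeffs <- function(A, Rd, Cm, cst) {
  Rm <- cst$rm_fraction * Rd
  Os <- cst$alpha * A / (0.047 * cst$gbs) + cst$Om
  III <- (cst$x - cst$x^2) / (6 * A)
  II <- (1 - cst$x) / 3 *
    (cst$gbs / A * (Cm - Rm / cst$gbs - cst$gamma_star * cst$Om) - 1 -
       cst$alpha * cst$gamma_star / 0.047) -
    cst$x / 2 * (1 + Rd / A)
  I <- (1 + Rd / A) * (Rm - cst$gbs * Cm -
                         7 * cst$gbs * cst$gamma_star * cst$Om / 3) +
    (Rd + A) * (1 - 7 * cst$alpha * cst$gamma_star / (3 * 0.047))
  list(I = I, II = II, III = III)
}

test_that("the electron-transport root satisfies the quadratic", {
  st <- random_states(500, seed = 11)
  for (alpha in c(0, 0.1)) {
    cst <- c4_constants(alpha = alpha)
    Jt <- electron_transport(st$A, st$Rd, st$Ci, cst)
    expect_true(all(is.finite(Jt)))
    q <- quad_coeffs(st$A, st$Rd, st$Ci, cst)
    resid <- (q$III * Jt^2 + q$II * Jt + q$I) / (abs(q$I) + 1)
    expect_lt(max(abs(resid)), 1e-8)
    # admissibility of the chosen root
    expect_true(all((1 - cst$x) * Jt / 3 > st$A + st$Rd))
  }
})

test_that("electron transport increases with assimilation", {
  A <- seq(5, 40, by = 0.5)
  Jt <- electron_transport(A, Rd = 1.5, Cm = 300)
  expect_true(all(diff(Jt) > 0))
  # a dark record (A + Rd <= 0) has no admissible root and is flagged
  expect_true(is.na(suppressWarnings(electron_transport(-2, 1, 300))))
})

test_that("the bundle-sheath state obeys its defining identities", {
  cst <- c4_constants()
  st <- bundle_sheath_state(A = 15, Rd = 1.5, Jt = 100, cst)
  expect_equal(st$Vp, 20)            # x Jt / 2 with x = 0.4
  expect_equal(st$Os, 210000)        # alpha = 0 -> Os = Om
  expect_equal(st$Vc - 0.5 * st$Vo - 1.5, 15, tolerance = 1e-10)

  # conservation across random admissible states
  s <- random_states(200, seed = 12)
  Jt <- electron_transport(s$A, s$Rd, s$Ci, cst)
  bs <- bundle_sheath_state(s$A, s$Rd, Jt, cst)
  expect_lt(max(abs(bs$Vc - 0.5 * bs$Vo - s$Rd - s$A)), 1e-10)
  expect_true(all(bs$Cbs > 0 & bs$Vc >= 0 & bs$Vo >= 0))

  # inadmissible Jt flagged, not computed
  expect_true(is.na(bundle_sheath_state(30, 1.5, Jt = 100, cst)$Cbs))
})

test_that("diffusional fractionation weights boundary layer and stomata", {
  expect_equal(combined_a_prime(450, 450, 300), 4.4)  # all stomatal
  expect_equal(combined_a_prime(450, 300, 300), 2.9)  # all boundary layer
  expect_equal(combined_a_prime(450, 375, 300), 3.65) # midway
  expect_true(is.na(combined_a_prime(450, 400, 450)))
})

test_that("ternary factor uses the fractional a-prime convention", {
  expect_equal(ternary_t(4.4, 0.004, 0.4), (1 + 0.0044) * 0.004 / 0.8)
  expect_equal(ternary_t(4.4, 0, 0.4), 0)
  # linear in E
  expect_equal(ternary_t(4.4, 0.008, 0.4), 2 * ternary_t(4.4, 0.004, 0.4))
  expect_true(is.na(ternary_t(4.4, 0.004, 0)))
  # permil-literal variant for sensitivity checks
  cst <- c4_constants(ternary_permil_literal = TRUE)
  expect_equal(ternary_t(4.4, 0.004, 0.4, cst), 5.4 * 0.004 / 0.8)
})

test_that("temperature and source-air fractionation terms evaluate", {
  expect_equal(b4_prime(27), -9483 / 300 + 26.09)
  expect_equal(b4_prime(25), -9483 / 298 + 26.09)
  expect_true(all(diff(b4_prime(seq(5, 45, 5))) > 0))
  expect_equal(e_prime(-8), 0)
  expect_equal(e_prime(-6.5), 1.5)
  expect_warning(ep <- e_prime(-10.5), "range")
  expect_equal(ep, -2.5)
})

test_that("effective fractionations fold respiration and photorespiration", {
  st <- data.frame(Vc = 30, Vo = 0, Vp = 20)
  bb <- b3_b4(st, e_prime = 0, Rd = 1.5, Tleaf_C = 27)
  expect_equal(bb$b3, 30)            # collapses to b3-prime
  expect_equal(bb$b4, b4_prime(27))  # e-prime = 0 -> b4 = b4-prime
  # b3 decreases by f Vo / Vc
  st2 <- data.frame(Vc = 30, Vo = 3, Vp = 20)
  bb2 <- b3_b4(st2, e_prime = 0, Rd = 1.5, Tleaf_C = 27)
  expect_equal(bb$b3 - bb2$b3, 11.6 * 3 / 30)
  # flagged when rates are non-positive
  expect_true(is.na(b3_b4(data.frame(Vc = 0, Vo = 0, Vp = 20),
                          0, 1.5, 27)$b3))
})

test_that("leakiness inverts the forward discrimination exactly", {
  cst <- c4_constants()
  s <- random_states(400, seed = 13)
  Jt <- electron_transport(s$A, s$Rd, s$Ci, cst)
  bs <- bundle_sheath_state(s$A, s$Rd, Jt, cst)
  ap <- combined_a_prime(s$Ca, s$Cs, s$Ci, cst)
  tern <- ternary_t(ap, s$E, s$gact, cst)
  bb <- b3_b4(bs, e_prime(s$delta_ref, cst), s$Rd, s$Tleaf, cst)
  for (phi0 in c(0.05, 0.2, 0.4)) {
    D <- forward_discrimination(phi0, s$Ca, s$Ci, bs$Cbs, tern, ap,
                                bb$b3, bb$b4, cst)
    phi <- leakiness(D, s$Ca, s$Ci, bs$Cbs, tern, ap, bb$b3, bb$b4, cst)
    expect_lt(max(abs(phi - phi0)), 1e-9)
  }
  # per-state prescribed phi round-trips too
  D <- forward_discrimination(s$phi, s$Ca, s$Ci, bs$Cbs, tern, ap,
                              bb$b3, bb$b4, cst)
  phi <- leakiness(D, s$Ca, s$Ci, bs$Cbs, tern, ap, bb$b3, bb$b4, cst)
  expect_lt(max(abs(phi - s$phi)), 1e-9)
})

test_that("phi is monotone in the observed discrimination", {
  cst <- c4_constants()
  Jt <- electron_transport(30, 1.5, 350, cst)
  bs <- bundle_sheath_state(30, 1.5, Jt, cst)
  ap <- combined_a_prime(500, 490, 350, cst)
  tern <- ternary_t(ap, 0.005, 0.3, cst)
  bb <- b3_b4(bs, 0, 1.5, 27, cst)
  D <- seq(1, 8, by = 0.25)
  phi <- leakiness(D, 500, 350, bs$Cbs, tern, ap, bb$b3, bb$b4, cst)
  expect_true(all(diff(phi) > 0))
  # and dDelta/dphi keeps one sign over (0, 0.6)
  ph <- seq(0.02, 0.6, by = 0.02)
  Df <- forward_discrimination(ph, 500, 350, bs$Cbs, tern, ap,
                               bb$b3, bb$b4, cst)
  expect_true(all(diff(Df) > 0))
  # implausible estimates are flagged, never clipped
  big <- leakiness(60, 500, 350, bs$Cbs, tern, ap, bb$b3, bb$b4, cst)
  expect_true(attr(big, "implausible")[1])
})

test_that("the ATP cost model reproduces the overcycling arithmetic", {
  expect_equal(atp_cost(0), 5)
  expect_equal(round(atp_cost(c(0.2, 0.25, 0.3)), 1), c(5.5, 5.7, 5.9))
  expect_error(atp_cost(1), "phi")
  # convex and increasing on [0, 1)
  ph <- seq(0, 0.9, by = 0.05)
  cost <- atp_cost(ph)
  expect_true(all(diff(cost) > 0))
  expect_true(all(diff(diff(cost)) > 0))
})
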