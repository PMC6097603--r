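test_that("geometry factors have the exact values and limits", {
  g <- geometry_factors(h = 9.19e-6, ell = 9.19e-6)  # beta = 2
  expect_equal(g$beta, 2)
  expect_equal(g$X, 0.4472136, tolerance = 1e-6)
  expect_equal(g$A, 0.3739010, tolerance = 1e-6)
  expect_equal(g$B, 1.0178885, tolerance = 1e-6)
  # screening limit beta -> 0 and bulk limit beta -> infinity
  g0 <- geometry_factors(h = 1e-2 / 2, ell = 1)      # beta = 1e-2
  expect_lt(max(abs(c(g0$A, g0$B))), 1e-3)
  g1 <- geometry_factors(h = 1e4 / 2, ell = 1)       # beta = 1e4
  expect_lt(max(abs(c(g1$A, g1$B) - 1)), 1e-3)
  # approach to the bulk limit is O(1/beta): A(1e3) is within 2e-3 of 1
  g2 <- geometry_factors(h = 1e3 / 2, ell = 1)
  expect_lt(abs(g2$A - 1), 2e-3)
  expect_error(geometry_factors(-1, 1), "positive")
})

test_that("averaged pair equation: fixed point, sign, and drift equivalence", {
  p <- reference_pair()
  p1 <- p; p1$D <- 1
  expect_equal(adler_rhs(0, p1), 0)
  # leading rotor is slowed: chi decreases at chi = pi/2 for identical rotors
  expect_lt(adler_rhs(pi / 2, p1), 0)

  # time-averaged drift from integrating the phase equation equals the
  # closed form: average speed = 2*pi / period, period = integral dchi/rhs
  for (D in c(1.15, 1.18, 1.25, 1.3)) {
    pd <- p; pd$D <- D
    closed <- average_drift(pd)
    expect_gt(closed, 0)
    period <- stats::integrate(function(chi) 1 / adler_rhs(chi, pd),
                               0, 2 * pi, rel.tol = 1e-10)$value
    expect_lt(abs(2 * pi / period - closed), 1e-6)
  }
})

test_that("locked branch is exactly zero and opens at the critical detuning", {
  p <- reference_pair()
  Dstar <- critical_detuning(p)
  expect_equal(average_drift(p, D = c(1, Dstar * 0.999)), c(0, 0))
  expect_gt(average_drift(p, D = Dstar * 1.001), 0)
  # drift is monotone in D beyond the boundary
  D <- seq(Dstar + 1e-3, Dstar + 0.2, length.out = 30)
  expect_true(all(diff(average_drift(p, D = D)) > 0))
  # rigid orbits: coupling term vanishes, drift equals bare detuning
  pr <- p; pr$lambda <- p$lambda * 1e9; pr$D <- 1.05
  expect_equal(average_drift(pr),
               diff(intrinsic_frequency(pr)), tolerance = 1e-6)
})

test_that("critical detuning: closed form, bisection oracle, monotonicity", {
  p <- reference_pair()
  expect_equal(critical_detuning(p, h = 4.2e-6), 1.1346, tolerance = 1e-3)
  # independent bisection on average_drift(D) = 0+
  bisect <- function(h) {
    ph <- p; ph$h <- h
    lo <- 1; hi <- 3
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (average_drift(ph, D = mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  for (h in c(4.2e-6, 16.7e-6, 51.7e-6)) {
    expect_equal(critical_detuning(p, h = h), bisect(h), tolerance = 1e-5)
  }
  # rigid limit
  pr <- p; pr$lambda <- p$lambda * 1e12
  expect_equal(critical_detuning(pr), 1, tolerance = 1e-5)
  # stronger coupling away from the wall -> larger D*
  h_grid <- seq(4.2e-6, 51.7e-6, length.out = 25)
  expect_true(all(diff(critical_detuning(p, h = h_grid)) > 0))
})

test_that("near-threshold drift follows the saddle-node square root", {
  p <- reference_pair()
  Dstar <- critical_detuning(p)
  eps <- 10^seq(-5, -3, length.out = 10)
  drift <- average_drift(p, D = Dstar * (1 + eps))
  slope <- unname(stats::coef(stats::lm(log(drift) ~ log(eps)))[2])
  expect_equal(slope, 0.5, tolerance = 0.02)
})

test_that("theory-mode bifurcation scan matches average_drift and flags locking", {
  p <- reference_pair()
  sc <- pair_bifurcation_scan(p, D_grid = seq(1, 1.2, by = 0.01))
  expect_s3_class(sc, "pair_scan")
  expect_equal(sc$drift, average_drift(p, D = sc$D))
  expect_true(all(sc$locked == (sc$D < critical_detuning(p))))
})

test_that("simulated synchronization boundary sits slightly above the theory", {
  p <- reference_pair(t_end = 250, t_burn = 50)
  Dstar <- critical_detuning(p)
  # just under the theoretical boundary: both locked; just above: the full
  # simulation still locks (its boundary overestimates), well above: drifts
  sc <- pair_bifurcation_scan(p, D_grid = c(Dstar - 0.01, Dstar + 0.01,
                                            Dstar + 0.06),
                              mode = "simulation")
  expect_true(sc$locked[1])
  expect_true(sc$locked[2])
  expect_false(sc$locked[3])
})

test_that("coupling fractions are exact and normalized", {
  expect_equal(coupling_fraction(1, j = 3), 0.8434, tolerance = 1e-4)
  expect_equal(coupling_fraction(1, j = 1), 0.4380, tolerance = 1e-4)
  for (j in c(0.5, 1, 2, 3)) {
    expect_equal(sum(coupling_fraction(1:5, j = j)), 1)
  }
  expect_error(coupling_fraction(0, j = 1), "1..n_max")
  expect_error(coupling_fraction(6, j = 1), "1..n_max")
})

test_that("neighbor coupling profile interpolates the two power-law limits", {
  p <- rotor_params(N = 6)
  # near-wall limit: r^-3 fractions
  near <- neighbor_coupling_profile(p, h = p$ell / 1e3)
  expect_equal(near$fraction, coupling_fraction(1:5, j = 3), tolerance = 1e-3)
  # bulk limit: r^-1 fractions
  far <- neighbor_coupling_profile(p, h = 1e3 * p$ell)
  expect_equal(far$fraction, coupling_fraction(1:5, j = 1), tolerance = 1e-3)
  # nearest-neighbor share decreases monotonically with height
  s1 <- vapply(c(4.2, 6.7, 11.7, 16.7, 31.7, 51.7) * 1e-6,
               function(h) neighbor_coupling_profile(p, h = h)$fraction[1],
               numeric(1))
  expect_true(all(diff(s1) < 0))
})
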