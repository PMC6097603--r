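test_that("phase differences: constant case, inserted step, round trip", {
  # identical constant-frequency rotors -> chi constant
  traj <- make_linear_traj(w = c(7, 7, 7), offset = c(0, 0.4, 0.8))
  chi <- phase_differences(traj)
  expect_true(all(abs(chi$chi - 0.4) < 1e-12))

  # one inserted 2*pi step shows as exactly one 2*pi ramp
  time <- seq(0, 50, by = 0.01)
  phi1 <- 7 * time
  phi2 <- 7 * time + 2 * pi * stats::plogis((time - 25) / 0.5)
  chi2 <- phase_differences(make_traj(time, cbind(phi1, phi2)))
  expect_equal(chi2$chi[1], 0, tolerance = 1e-6)
  expect_equal(chi2$chi[length(time)], 2 * pi, tolerance = 1e-6)

  # unwrap(wrap(x)) recovers a smooth series up to the starting branch
  x <- 5 * time + 2 * sin(time / 3)
  wrapped <- (x %% (2 * pi))
  chi3 <- phase_differences(make_traj(time, cbind(x * 0, wrapped)))
  expect_equal(chi3$chi, x - x[1], tolerance = 1e-9)
})

test_that("undersampled trajectories are rejected", {
  traj <- make_linear_traj(t_end = 50, dt = 0.5, w = c(7, 7))  # ~2 samples/period
  expect_error(phase_differences(traj), "undersampled")
})

test_that("slip detection counts monotone 2*pi excursions with direction", {
  # locked: no slips
  locked <- make_linear_traj(w = c(7, 7), offset = c(0, 0.6))
  expect_equal(nrow(detect_slips(locked)), 0)

  # steady drift: one slip per 2*pi of relative phase
  time <- seq(0, 100, by = 0.01)
  drift_rate <- 0.5
  traj <- make_traj(time, cbind(7 * time, 7 * time + drift_rate * time))
  ev <- detect_slips(traj)
  expect_equal(nrow(ev), floor(drift_rate * 100 / (2 * pi)))
  expect_true(all(ev$direction == 1))
  expect_true(all(ev$kind == "slip"))

  # sub-2*pi oscillation across a level is not a slip
  wob <- make_traj(time, cbind(7 * time, 7 * time + 3 * sin(0.3 * time)))
  expect_equal(nrow(detect_slips(wob)), 0)
})

test_that("slip detection is invariant under global phase shift and flips under time reversal", {
  time <- seq(0, 100, by = 0.01)
  phi <- cbind(7 * time, 7 * time + 0.4 * time)
  ev <- detect_slips(make_traj(time, phi))
  ev_shift <- detect_slips(make_traj(time, phi + 1.23))
  expect_equal(ev$time, ev_shift$time)
  expect_equal(ev$direction, ev_shift$direction)
  # reversed trajectory: same number of slips, opposite direction
  ev_rev <- detect_slips(make_traj(time, phi[rev(seq_along(time)), ]))
  expect_equal(nrow(ev_rev), nrow(ev))
  expect_true(all(ev_rev$direction == -ev$direction[1]))
})

test_that("slip count times 2*pi matches the net chi change within one slip", {
  p <- rotor_params(N = 2, h = 4.2e-6, D = 1.25, t_end = 150, t_burn = 0)
  traj <- simulate_rotors(p)
  chi <- phase_differences(traj)
  ev <- detect_slips(chi)
  net <- (chi$chi[nrow(chi)] - chi$chi[1]) / (2 * pi)
  expect_lt(abs(sum(ev$direction) - net), 1)
})

test_that("wobble detector: silent on locked waves, recovers injected pulses", {
  # clean metachronal wave: no wobbles
  mw <- make_linear_traj(t_end = 100, w = rep(7, 6), offset = 0.5 * (0:5))
  expect_equal(nrow(detect_wobbles(mw)), 0)

  # gaussian pulse of amplitude 1.2 rad on phi_1 -> one wobble, W = 1.2
  time <- seq(0, 100, by = 0.01)
  phi <- outer(time, rep(7, 4))
  phi[, 2] <- phi[, 2] + 1.2 * exp(-(time - 50)^2 / (2 * 1.5^2))
  ev <- detect_wobbles(make_traj(time, phi))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$W, 1.2, tolerance = 0.05)
  expect_true(is.na(ev$slip_at))

  # two pulses -> recurrence time between onsets
  phi2 <- outer(time, rep(7, 2))
  for (t0 in c(30, 70)) {
    phi2[, 2] <- phi2[, 2] + 1.5 * exp(-(time - t0)^2 / (2 * 1.5^2))
  }
  ev2 <- detect_wobbles(make_traj(time, phi2))
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$tau[2], 40, tolerance = 0.1)
})

test_that("simulated chain at intermediate height wobbles on a ~10-period clock", {
  p <- rotor_params(N = 6, h = 11.7e-6, experimental_lambda = TRUE,
                    t_end = 300, t_burn = 0)
  traj <- simulate_rotors(p)
  ev <- detect_wobbles(traj)
  expect_gt(nrow(ev), 2)
  Tm <- mean_period(p)
  tau_beats <- stats::median(ev$tau, na.rm = TRUE) / Tm
  expect_gt(tau_beats, 2)
  expect_lt(tau_beats, 50)
})

test_that("order parameter identifies uniform waves and chevrons", {
  # all differences zero: A = 1, Psi = 0
  z0 <- order_parameter(make_linear_traj(w = rep(7, 6)), t_burn = 0)
  expect_equal(attr(z0, "A_bar"), 1, tolerance = 1e-12)
  expect_equal(attr(z0, "Psi_bar_abs"), 0, tolerance = 1e-12)

  # uniform wave chi_n = c: A = 1, Psi = c
  zc <- order_parameter(make_linear_traj(w = rep(7, 6), offset = 0.7 * (0:5)),
                        t_burn = 0)
  expect_equal(attr(zc, "A_bar"), 1, tolerance = 1e-12)
  expect_equal(attr(zc, "Psi_bar_abs"), 0.7, tolerance = 1e-12)

  # symmetric chevron: differences +c,+c,-c,-c -> Psi = 0, A < 1
  off <- cumsum(c(0, 0.8, 0.8, -0.8, -0.8))
  zch <- order_parameter(make_linear_traj(w = rep(7, 5), offset = off),
                         t_burn = 0)
  expect_equal(attr(zch, "Psi_bar_abs"), 0, tolerance = 1e-12)
  expect_lt(attr(zch, "A_bar"), 1)

  # A = 1 iff all pairwise differences are equal
  off2 <- cumsum(c(0, 0.5, 0.5001, 0.5))
  za <- order_parameter(make_linear_traj(w = rep(7, 4), offset = off2),
                        t_burn = 0)
  expect_lt(attr(za, "A_bar"), 1)
  expect_gt(attr(za, "A_bar"), 1 - 1e-6)
})

test_that("drift per beat: zero when locked, matches pair theory when drifting", {
  locked <- make_linear_traj(t_end = 300, w = rep(7, 6), offset = 0.3 * (0:5))
  expect_equal(drift_per_beat(locked, t_burn = 10), 0, tolerance = 1e-12)

  p <- rotor_params(N = 2, h = 4.2e-6, D = 1.25, t_end = 400, t_burn = 50)
  traj <- simulate_rotors(p)
  dpb <- drift_per_beat(traj)
  chi_rate <- average_drift(p)
  # beats measured on the actual (coupled) rotation rate
  sel <- which(traj$time > p$t_burn)
  span <- traj$time[max(sel)] - traj$time[min(sel)]
  w_meas <- ((traj$phi_0[max(sel)] - traj$phi_0[min(sel)]) +
             (traj$phi_1[max(sel)] - traj$phi_1[min(sel)])) / (2 * span)
  expect_equal(dpb, chi_rate / w_meas, tolerance = 0.05)
})

test_that("kymograph export is a bounded rotor-by-time matrix", {
  traj <- make_linear_traj(t_end = 10, w = c(7, 7, 7))
  km <- kymograph(traj)
  expect_equal(dim(km), c(3, length(attr(km, "time"))))
  expect_true(all(abs(km) <= 1))
  expect_true(all(km[, 1] == sin(0)))
  one <- kymograph(make_traj(seq(0, 1, 0.01), cbind(rep(0, 101))))
  expect_equal(dim(one)[1], 1)
  expect_true(all(one == 0))
})
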