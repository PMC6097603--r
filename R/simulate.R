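#' In-plane external force on one rotor
#'
#' The optical trap exerts a constant tangential driving force of magnitude
#' `F_i = F_dr * D^(i - 0.5)` and a radial restoring force
#' `-lambda (rho_i - R)` from the harmonic potential about the prescribed
#' orbit radius. Both act in the orbit plane; the wall-normal component is
#' zero.
#'
#' @param params A [rotor_params()] object.
#' @param i Zero-based rotor index.
#' @param phi Orbital phase (rad).
#' @param rho Radial distance of the bead from its orbit center (m, > 0).
#' @return Force vector `c(Fx, Fy, Fz = 0)` (N) in lab coordinates, with the
#'   orbit center at the origin of the local x-y frame.
#' @export
external_force <- function(params, i, phi, rho) {
  stopifnot(inherits(params, "rotor_params"))
  if (!is.finite(rho) || rho <= 0)
    stop("`rho` must be positive (tangent direction undefined at rho = 0)",
         call. = FALSE)
  Fd <- driving_force(params, i)
  Fr <- -effective_lambda(params) * (rho - params$R)
  c(-Fd * sin(phi) + Fr * cos(phi),
    Fd * cos(phi) + Fr * sin(phi),
    0)
}

#' Time derivatives of the rotor-chain state
#'
#' Reference implementation of the equations of motion, written with
#' [mobility_velocities()] and [external_force()]: bead velocities follow
#' from the force balance between viscous drag and the trap forces, with
#' hydrodynamic coupling through the wall Green's function evaluated at the
#' instantaneous bead positions. Motion is confined to the orbit plane at
#' height `h` (the traps prescribe a planar array of circles), so
#' wall-normal velocity components are discarded and the state per rotor is
#' `(phi_i, rho_i)` with `phi_dot = v_t / rho` and `rho_dot = v_r`.
#'
#' [simulate_rotors()] integrates an equivalent compiled version of this
#' function; the two are cross-checked in the package tests.
#'
#' @param t Time (s); the dynamics are autonomous, `t` is ignored.
#' @param state Numeric vector `c(phi_0..phi_{N-1}, rho_0..rho_{N-1})`.
#' @param params A [rotor_params()] object.
#' @return A list whose first element is the derivative vector, as expected
#'   by [deSolve::ode()].
#' @export
rotor_rhs <- function(t, state, params) {
  stopifnot(inherits(params, "rotor_params"))
  N <- params$N
  if (length(state) != 2L * N)
    stop("`state` must have length 2N", call. = FALSE)
  phi <- state[seq_len(N)]
  rho <- state[N + seq_len(N)]
  if (any(rho <= 0)) stop("`rho` must stay positive", call. = FALSE)

  pos <- cbind((seq_len(N) - 1L) * params$ell + rho * cos(phi),
               rho * sin(phi),
               params$h)
  f <- t(vapply(seq_len(N),
                function(i) external_force(params, i - 1L, phi[i], rho[i]),
                numeric(3)))
  v <- as.matrix(mobility_velocities(pos, f, params$mu, params$a,
                                     truncation = params$truncation))
  vt <- -v[, 1] * sin(phi) + v[, 2] * cos(phi)
  vr <- v[, 1] * cos(phi) + v[, 2] * sin(phi)
  list(unname(c(vt / rho, vr)))
}

#' Simulate a chain of hydrodynamically coupled rotors
#'
#' Integrates the deterministic equations of motion for `N` driven rotors on
#' compliant circular orbits at height `h` above a no-slip wall, coupled
#' through the wall Green's function (optionally truncated to nearest
#' neighbors). Uses [deSolve::ode()] (`lsoda`) with a compiled right-hand
#' side, relative tolerance `params$rtol` and absolute tolerance
#' `params$atol`, and samples the output densely enough to resolve
#' individual beats (`params$samples_per_period` per mean period).
#'
#' Initial radial excursions are `rho_i = R` exactly; initial phases are
#' drawn uniformly on `[0, 2 pi)` from `params$seed` unless `phi0` is given.
#' The run is deterministic given `(params, phi0)`.
#'
#' @param params A [rotor_params()] object.
#' @param phi0 Optional numeric vector of `N` initial phases (rad).
#' @return A tibble of class `rotor_trajectory` with columns `time`,
#'   `phi_0..phi_{N-1}` (continuous, unbounded phases, rad) and
#'   `rho_0..rho_{N-1}` (m). The generating parameters are attached as
#'   attribute `"params"`.
#' @examples
#' \donttest{
#' p <- rotor_params(N = 2, D = 1, h = 4.2e-6, t_end = 30, t_burn = 0)
#' traj <- simulate_rotors(p)
#' glance(traj)
#' }
#' @export
simulate_rotors <- function(params, phi0 = NULL) {
  stopifnot(inherits(params, "rotor_params"))
  N <- params$N
  if (is.null(phi0)) {
    phi0 <- withr::with_seed(params$seed, stats::runif(N, 0, 2 * pi))
  }
  phi0 <- as.numeric(phi0)
  if (length(phi0) != N || !all(is.finite(phi0)))
    stop("`phi0` must be a finite numeric vector of length N", call. = FALSE)

  Tm <- mean_period(params)
  dt <- Tm / params$samples_per_period
  times <- seq(0, params$t_end, by = dt)
  parms <- c(N, params$a, params$R, params$ell, params$h, params$mu,
             effective_lambda(params),
             as.numeric(params$truncation == "nearest_neighbor"),
             driving_force(params), rep(0, 64L - N))
  y0 <- c(phi0, rep(params$R, N))

  out <- tryCatch(
    deSolve::ode(y = y0, times = times, func = "rotor_derivs", parms = parms,
                 dllname = "rotorwave", initfunc = "rotor_initmod",
                 method = "lsoda", rtol = params$rtol, atol = params$atol),
    error = function(e) {
      stop("rotor-chain integration failed (N = ", N, ", h = ", params$h,
           " m, lambda = ", effective_lambda(params), " N/m): ",
           conditionMessage(e), call. = FALSE)
    })
  if (attr(out, "istate")[1] < 0)
    stop("rotor-chain integration did not complete to t_end = ",
         params$t_end, " s", call. = FALSE)

  res <- tibble::as_tibble(as.data.frame(out))
  names(res) <- c("time",
                  paste0("phi_", seq_len(N) - 1L),
                  paste0("rho_", seq_len(N) - 1L))
  attr(res, "params") <- params
  attr(res, "phi0") <- phi0
  class(res) <- c("rotor_trajectory", class(res))
  res
}

#' Retrieve the parameters attached to a trajectory
#'
#' @param traj A `rotor_trajectory` tibble from [simulate_rotors()] or
#'   [read_trajectory()].
#' @return The [rotor_params()] object stored with the trajectory.
#' @export
trajectory_params <- function(traj) {
  p <- attr(traj, "params")
  if (is.null(p))
    stop("`traj` carries no parameter attribute; was it created by ",
         "simulate_rotors() or read_trajectory()?", call. = FALSE)
  p
}

#' @describeIn simulate_rotors Long-format view of a trajectory: one row per
#'   `(time, rotor)` with columns `time`, `rotor`, `phi`, `rho`.
#' @param x A `rotor_trajectory`.
#' @param ... Unused.
#' @export
tidy.rotor_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = c(".value", "rotor"), names_sep = "_") |>
    dplyr::mutate(rotor = as.integer(.data$rotor)) |>
    dplyr::arrange(.data$time, .data$rotor)
}

#' @describeIn simulate_rotors One-row summary: rotor count, horizon,
#'   end-to-end drift per beat, time-averaged order parameter and slip count.
#' @export
glance.rotor_trajectory <- function(x, ...) {
  p <- trajectory_params(x)
  n_slips <- nrow(detect_slips(x))
  if (p$N >= 2) {
    op <- order_parameter(x, t_burn = p$t_burn)
    A_bar <- attr(op, "A_bar"); Psi_bar_abs <- attr(op, "Psi_bar_abs")
    dpb <- drift_per_beat(x, t_burn = p$t_burn)
  } else {
    A_bar <- NA_real_; Psi_bar_abs <- NA_real_; dpb <- NA_real_
  }
  tibble::tibble(N = p$N, t_end = p$t_end, drift_per_beat = dpb,
                 A_bar = A_bar, Psi_bar_abs = Psi_bar_abs, n_slips = n_slips)
}
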