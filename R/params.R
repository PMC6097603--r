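#' Physical parameters for a rotor-chain scenario
#'
#' Bundles every physical constant and model switch needed to simulate a
#' linear chain of driven colloidal rotors above a no-slip wall. All
#' quantities are in SI units; the defaults are the optical-tweezer bead
#' array studied experimentally (silica beads of radius 1.74 um driven on
#' orbits of radius 1.59 um spaced 9.19 um apart in a fluid of viscosity
#' 6 mPa s).
#'
#' The radial trap stiffness `lambda` is the knob that makes orbits
#' compliant and thereby enables hydrodynamic phase adjustment. Feedback
#' delays in the optical traps mean that an experimentally calibrated
#' stiffness corresponds to a larger effective simulation stiffness; setting
#' `experimental_lambda = TRUE` multiplies `lambda` by `gamma` before use.
#'
#' @param a Bead radius (m).
#' @param R Orbit (trap) radius (m).
#' @param ell Center-to-center rotor spacing (m).
#' @param h Height of the orbit plane above the wall (m); must exceed `a`.
#' @param mu Dynamic viscosity of the suspending fluid (Pa s).
#' @param lambda Radial spring constant of the orbit (N/m). The experimental
#'   value 2.06 pN/um is `2.06e-6`.
#' @param F_dr Driving force scale (N); rotor `i` is driven tangentially with
#'   magnitude `F_dr * D^(i - 0.5)`.
#' @param D Detuning factor (dimensionless, > 0). `D = 1` gives identical
#'   rotors; `D = 1.01` gives a 5% intrinsic frequency spread across six
#'   rotors and breaks left-right symmetry so a metachronal wave forms.
#' @param N Number of rotors (1 to 64).
#' @param truncation Coupling truncation: `"none"` keeps all pairwise
#'   hydrodynamic interactions, `"nearest_neighbor"` keeps only `|i - j| = 1`.
#' @param t_end Integration horizon (s).
#' @param t_burn Burn-in discarded by time-averaged diagnostics (s).
#' @param seed Integer seed used to draw random initial phases.
#' @param experimental_lambda If `TRUE`, interpret `lambda` as the
#'   experimentally calibrated stiffness and use `gamma * lambda` in the
#'   dynamics.
#' @param gamma Feedback-delay correction factor applied when
#'   `experimental_lambda` is `TRUE`.
#' @param samples_per_period Output samples per mean rotation period.
#' @param rtol,atol Relative and absolute integrator tolerances.
#'
#' @return An object of class `rotor_params` (a named list).
#' @examples
#' p <- rotor_params(h = 11.7e-6, N = 6)
#' p
#' driving_force(p)
#' @export
rotor_params <- function(a = 1.74e-6,
                         R = 1.59e-6,
                         ell = 9.19e-6,
                         h = 11.7e-6,
                         mu = 6e-3,
                         lambda = 2.06e-6,
                         F_dr = 2.23e-12,
                         D = 1.01,
                         N = 6L,
                         truncation = c("none", "nearest_neighbor"),
                         t_end = 2000,
                         t_burn = 200,
                         seed = 1L,
                         experimental_lambda = FALSE,
                         gamma = 2.21,
                         samples_per_period = 100,
                         rtol = 1e-8,
                         atol = 1e-10) {
  truncation <- match.arg(truncation)
  for (nm in c("a", "R", "ell", "h", "mu", "lambda", "F_dr", "D", "gamma",
               "t_end", "samples_per_period", "rtol", "atol")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
  }
  N <- as.integer(N)
  if (is.na(N) || N < 1L || N > 64L)
    stop("`N` must be an integer between 1 and 64", call. = FALSE)
  if (h <= a)
    stop("invalid geometry: orbit height `h` must exceed the bead radius `a`",
         call. = FALSE)
  if (R >= ell / 2)
    stop("orbit radius `R` must be smaller than `ell`/2 so orbits do not touch",
         call. = FALSE)
  if (t_burn < 0 || t_burn >= t_end)
    stop("`t_burn` must lie in [0, t_end)", call. = FALSE)
  p <- list(
    a = a, R = R, ell = ell, h = h, mu = mu,
    lambda = lambda, F_dr = F_dr, D = D, N = N,
    truncation = truncation, t_end = t_end, t_burn = t_burn,
    seed = as.integer(seed),
    experimental_lambda = isTRUE(experimental_lambda), gamma = gamma,
    samples_per_period = samples_per_period, rtol = rtol, atol = atol
  )
  class(p) <- "rotor_params"
  p
}

#' Effective radial stiffness used in the dynamics
#'
#' Returns `lambda`, or `gamma * lambda` when the parameters were declared as
#' experimentally calibrated (`experimental_lambda = TRUE`).
#'
#' @param params A [rotor_params()] object.
#' @return Stiffness (N/m).
#' @export
effective_lambda <- function(params) {
  stopifnot(inherits(params, "rotor_params"))
  if (params$experimental_lambda) params$gamma * params$lambda else params$lambda
}

#' @export
print.rotor_params <- function(x, ...) {
  cat("<rotor_params>\n")
  cat(sprintf("  N = %d rotors, D = %g, truncation = %s\n",
              x$N, x$D, x$truncation))
  cat(sprintf("  a = %.3g um, R = %.3g um, ell = %.3g um, h = %.3g um\n",
              x$a * 1e6, x$R * 1e6, x$ell * 1e6, x$h * 1e6))
  cat(sprintf("  mu = %.3g mPa s, lambda = %.3g pN/um%s, F_dr = %.3g pN\n",
              x$mu * 1e3, x$lambda * 1e6,
              if (x$experimental_lambda)
                sprintf(" (x gamma = %.3g effective)", effective_lambda(x) * 1e6)
              else "",
              x$F_dr * 1e12))
  cat(sprintf("  t_end = %g s, t_burn = %g s, seed = %d\n",
              x$t_end, x$t_burn, x$seed))
  invisible(x)
}

#' Tangential driving force on each rotor
#'
#' Rotor `i` (zero-based, `i = 0, ..., N-1`) is driven along its orbit by a
#' constant tangential force of magnitude `F_dr * D^(i - 0.5)`. The
#' geometric ladder in `D` detunes the intrinsic frequencies; across six
#' rotors with `D = 1.01` the end-to-end force (and frequency) ratio is
#' `D^5 = 1.051`, a 5% spread.
#'
#' @param params A [rotor_params()] object.
#' @param i Zero-based rotor indices (defaults to the whole chain).
#' @return Force magnitudes (N), one per element of `i`.
#' @examples
#' p <- rotor_params(N = 6)
#' driving_force(p, 0)
#' driving_force(p, 5) / driving_force(p, 0)  # D^5
#' @export
driving_force <- function(params, i = seq_len(params$N) - 1L) {
  stopifnot(inherits(params, "rotor_params"))
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 0L) || any(i >= params$N))
    stop("rotor index `i` must lie in 0..N-1", call. = FALSE)
  params$F_dr * params$D^(i - 0.5)
}

#' Intrinsic angular frequency of an isolated rotor
#'
#' An isolated rotor circulates at `omega_i = F_i / (R * zeta0 * zetaw(h))`,
#' where `zeta0 = 6 pi mu a` is the bulk Stokes drag and `zetaw` the
#' wall-proximity drag correction, so rotors beat faster far from the wall
#' and the period is `2 pi / omega_i` (of order one second for the default
#' bead array).
#'
#' @inheritParams driving_force
#' @return Angular velocities (rad/s).
#' @examples
#' p <- rotor_params(D = 1, h = 51.7e-6)
#' 2 * pi / intrinsic_frequency(p, 0)  # period in seconds
#' @export
intrinsic_frequency <- function(params, i = seq_len(params$N) - 1L) {
  stopifnot(inherits(params, "rotor_params"))
  zw <- wall_drag_correction(params$a, params$h)
  driving_force(params, i) / (params$R * bulk_drag(params$mu, params$a) * zw)
}

#' Mean rotation period of the chain
#'
#' `2 pi` divided by the mean intrinsic angular frequency; used to choose
#' output sampling and to express drift in beats.
#'
#' @param params A [rotor_params()] object.
#' @return Period (s).
#' @export
mean_period <- function(params) {
  2 * pi / mean(intrinsic_frequency(params))
}
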