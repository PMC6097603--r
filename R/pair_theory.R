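#' Wall-screening geometry factors
#'
#' The averaged two-rotor phase theory depends on height and spacing only
#' through `beta = 2h / ell` via
#' `X = 1/sqrt(1 + beta^2)`,
#' `A(beta) = 1 - X - (beta^2/2) X^3`, and
#' `B(beta) = 1 - X^3 + (3 beta^2/2) X^5`.
#' Both `A` and `B` vanish as `beta -> 0` (full screening at the wall) and
#' tend to 1 as `beta -> infinity` (bulk limit), so the combination
#' `2A + B` modulates the inter-rotor coupling strength with height.
#'
#' @param h Height(s) above the wall (m).
#' @param ell Rotor spacing(s) (m).
#' @return A tibble with columns `h`, `ell`, `beta`, `X`, `A`, `B`.
#' @examples
#' geometry_factors(h = 9.19e-6, ell = 9.19e-6)  # beta = 2
#' @export
geometry_factors <- function(h, ell) {
  if (!all(is.finite(h)) || !all(is.finite(ell)) || any(h <= 0) || any(ell <= 0))
    stop("`h` and `ell` must be positive", call. = FALSE)
  beta <- 2 * h / ell
  X <- 1 / sqrt(1 + beta^2)
  tibble::tibble(
    h = h + 0 * ell, ell = ell + 0 * h, beta = beta, X = X,
    A = 1 - X - beta^2 / 2 * X^3,
    B = 1 - X^3 + 3 * beta^2 / 2 * X^5
  )
}

# detuning term of the averaged pair equation (rad/s)
pair_detuning <- function(params, D = params$D) {
  stopifnot(inherits(params, "rotor_params"))
  zeta0 <- bulk_drag(params$mu, params$a)
  zetaw <- wall_drag_correction(params$a, params$h)
  (params$F_dr * (D^0.5 - D^(-0.5))) / (params$R * zeta0 * zetaw)
}

# coupling amplitude of the averaged pair equation (rad/s) for two rotors
# separated by `sep` (defaults to ell); purely geometric, no wall drag
pair_coupling <- function(params, D = params$D, sep = params$ell) {
  stopifnot(inherits(params, "rotor_params"))
  zeta0 <- bulk_drag(params$mu, params$a)
  g <- geometry_factors(params$h, sep)
  (3 * params$a / (4 * sep)) *
    (params$F_dr^2 / (effective_lambda(params) * zeta0 * params$R^2)) *
    (2 * g$A + g$B)
}

pair_terms <- function(params, D = params$D, sep = params$ell) {
  list(detuning = pair_detuning(params, D),
       coupling = pair_coupling(params, D, sep))
}

#' Averaged phase-difference dynamics of a rotor pair
#'
#' Right-hand side of the averaged evolution equation for the phase
#' difference `chi = phi_1 - phi_0` of two rotors a distance `ell` apart:
#' a constant detuning term `(F_1 - F_0) / (R zeta0 zetaw)` minus a
#' coupling term `(3a/4ell) (F_0 F_1 / (lambda zeta0 R^2)) (2A + B) sin(chi)`.
#' The coupling arises because orbit compliance lets each rotor's flow
#' advance or delay its neighbor: the leading rotor is slowed and the
#' lagging one sped up, so identical rotors synchronize while detuned ones
#' lock only if the coupling exceeds the detuning.
#'
#' @param chi Phase difference(s) (rad).
#' @param params A [rotor_params()] object (two-rotor semantics: the forces
#'   are `F_dr D^(-1/2)` and `F_dr D^(1/2)`).
#' @return `d chi / d t` (rad/s), one per element of `chi`.
#' @export
adler_rhs <- function(chi, params) {
  tm <- pair_terms(params)
  tm$detuning - tm$coupling * sin(chi)
}

#' Average phase drift of a detuned rotor pair
#'
#' Closed-form time average of [adler_rhs()] over one drift period: zero
#' while the pair is phase-locked (detuning not exceeding the coupling
#' amplitude), and `sqrt(detuning^2 - coupling^2)` beyond the saddle-node
#' bifurcation, so the drift grows as the square root of the excess
#' detuning.
#'
#' @param params A [rotor_params()] object.
#' @param D Optional detuning value(s) overriding `params$D`.
#' @return Average drift `d chi / d t` (rad/s), `>= 0` for `D >= 1`.
#' @examples
#' p <- rotor_params(h = 4.2e-6, N = 2)
#' average_drift(p, D = c(1, 1.1, 1.2))
#' @export
average_drift <- function(params, D = params$D) {
  tm <- pair_terms(params, D = D)
  drift2 <- tm$detuning^2 - tm$coupling^2
  ifelse(drift2 > 0, sign(tm$detuning) * sqrt(pmax(drift2, 0)), 0)
}

#' Critical detuning of the pair synchronization boundary
#'
#' The detuning `D*` at which the averaged pair theory loses its locked
#' state, found by equating detuning and coupling terms. With the geometric
#' force ladder `F_i = F_dr D^(i - 1/2)` the condition reads
#' `sqrt(D) - 1/sqrt(D) = C` with
#' `C = (3a/4ell) (F_dr zetaw / (lambda R)) (2A + B)`, whose explicit
#' solution is `D* = ((C + sqrt(C^2 + 4)) / 2)^2 > 1`. `D*` increases with
#' height: farther from the wall the coupling is stronger and the locked
#' state more robust.
#'
#' @param params A [rotor_params()] object.
#' @param h Height(s) (m); defaults to `params$h`.
#' @return Critical detuning(s) `D* > 1`.
#' @examples
#' p <- rotor_params(N = 2)
#' critical_detuning(p, h = c(4.2e-6, 51.7e-6))
#' @export
critical_detuning <- function(params, h = params$h) {
  stopifnot(inherits(params, "rotor_params"))
  vapply(h, function(hi) {
    zetaw <- wall_drag_correction(params$a, hi)
    g <- geometry_factors(hi, params$ell)
    C <- (3 * params$a / (4 * params$ell)) *
      (params$F_dr * zetaw / (effective_lambda(params) * params$R)) *
      (2 * g$A + g$B)
    ((C + sqrt(C^2 + 4)) / 2)^2
  }, numeric(1))
}

#' Drift-versus-detuning scan for a rotor pair
#'
#' Traces the saddle-node synchronization bifurcation of a rotor pair by
#' evaluating the averaged-theory drift and/or simulating the full
#' two-rotor hydrodynamic problem over a grid of detunings. Simulation
#' drift is the net slope of the unwrapped phase difference after burn-in;
#' a run is classified as phase-locked when it completes fewer than
#' `slip_threshold` slips over the horizon (the threshold is configurable
#' because the equivalent drift rate depends on the observation time).
#'
#' @param params A [rotor_params()] object; `N` is forced to 2.
#' @param D_grid Detunings to scan.
#' @param mode `"theory"`, `"simulation"`, or `"both"`.
#' @param slip_threshold Slip count at or above which a simulated run is
#'   classified as drifting (default 5).
#' @return A tibble of class `pair_scan` with columns `h`, `D`, `mode`,
#'   `drift` (rad/s), `n_slips` (NA for theory rows) and `locked`.
#' @examples
#' p <- rotor_params(h = 4.2e-6, N = 2)
#' pair_bifurcation_scan(p, D_grid = seq(1, 1.2, by = 0.05))
#' @export
pair_bifurcation_scan <- function(params, D_grid,
                                  mode = c("theory", "simulation", "both"),
                                  slip_threshold = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "rotor_params"))
  rows <- list()
  if (mode %in% c("theory", "both")) {
    drift <- average_drift(params, D = D_grid)
    rows$theory <- tibble::tibble(
      h = params$h, D = D_grid, mode = "theory", drift = drift,
      n_slips = NA_integer_, locked = drift == 0)
  }
  if (mode %in% c("simulation", "both")) {
    sim <- purrr::map(D_grid, function(Di) {
      p2 <- params; p2$D <- Di; p2$N <- 2L
      tryCatch({
        traj <- simulate_rotors(p2)
        chi <- phase_differences(traj)
        sel <- chi$time > p2$t_burn
        fit <- stats::coef(stats::lm(chi$chi[sel] ~ chi$time[sel]))[[2]]
        ns <- nrow(detect_slips(chi))
        tibble::tibble(h = p2$h, D = Di, mode = "simulation", drift = fit,
                       n_slips = as.integer(ns), locked = ns < slip_threshold)
      }, error = function(e) {
        warning("pair simulation failed at D = ", Di, ": ",
                conditionMessage(e), call. = FALSE)
        tibble::tibble(h = params$h, D = Di, mode = "simulation",
                       drift = NA_real_, n_slips = NA_integer_, locked = NA)
      })
    })
    rows$sim <- dplyr::bind_rows(sim)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pair_scan", class(out))
  out
}

#' Neighbor coupling fractions for a power-law flow decay
#'
#' If wall-parallel hydrodynamic disturbances decay with distance as
#' `r^(-j)`, the fraction of an end rotor's total coupling (to its first
#' `n_max` neighbors) carried by the `n`-th neighbor is
#' `S(n) = n^(-j) / sum_{i=1..n_max} i^(-j)`. Near the wall (`j = 3`)
#' interactions are nearest-neighbor dominated, `S(1) = 0.84`; far from it
#' (`j = 1`) long-range terms matter, `S(1) = 0.44`.
#'
#' @param n Neighbor order(s), integers in `1..n_max`.
#' @param j Positive decay exponent of the flow field.
#' @param n_max Number of neighbors summed in the normalization (default 5).
#' @return Fractions `S(n)`, summing to 1 over `n = 1..n_max`.
#' @examples
#' coupling_fraction(1, j = 3)
#' sum(coupling_fraction(1:5, j = 1))
#' @export
coupling_fraction <- function(n, j, n_max = 5L) {
  if (!is.numeric(j) || length(j) != 1L || !is.finite(j) || j <= 0)
    stop("`j` must be a single positive number", call. = FALSE)
  n <- as.integer(n)
  if (any(is.na(n)) || any(n < 1L) || any(n > n_max))
    stop("`n` must lie in 1..n_max", call. = FALSE)
  n^(-j) / sum(seq_len(n_max)^(-j))
}

#' Height-dependent neighbor coupling profile
#'
#' Evaluates the coupling amplitude of the averaged pair theory for rotor
#' separations `n * ell` (so `beta_n = 2h / (n ell)`) and normalizes over
#' the first `n_max` neighbors. Interpolates between the near-wall
#' `r^(-3)` profile ([coupling_fraction()] with `j = 3`) and the bulk
#' `r^(-1)` profile (`j = 1`): raising the rotors weakens the *relative*
#' weight of nearest-neighbor coupling even though every pairwise coupling
#' grows.
#'
#' @param params A [rotor_params()] object.
#' @param h Height (m); defaults to `params$h`.
#' @param n_max Number of neighbors (>= 2, default 5).
#' @return A tibble with columns `n`, `beta`, `amplitude` (rad/s) and
#'   `fraction`.
#' @export
neighbor_coupling_profile <- function(params, h = params$h, n_max = 5L) {
  stopifnot(inherits(params, "rotor_params"))
  if (n_max < 2L) stop("`n_max` must be at least 2", call. = FALSE)
  p <- params; p$h <- h
  n <- seq_len(n_max)
  amp <- vapply(n, function(ni) pair_coupling(p, sep = ni * p$ell),
                numeric(1))
  tibble::tibble(n = n, beta = 2 * h / (n * params$ell),
                 amplitude = amp, fraction = amp / sum(amp))
}
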