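# wrap an angle (or angle series) to (-pi, pi]
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

# continuous phase from a possibly wrapped series: undo jumps > pi between
# consecutive samples
unwrap_phase <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  x[1] + c(0, cumsum(wrap_angle(d)))
}

# samples-per-period estimate from the median wrapped phase increment
samples_per_period <- function(phi) {
  d <- abs(wrap_angle(diff(phi)))
  md <- stats::median(d)
  if (md == 0) Inf else 2 * pi / md
}

#' Unwrapped neighbor phase differences of a trajectory
#'
#' Computes the continuous phase differences `chi_n = phi_{n+1} - phi_n`
#' for `n = 0..N-2` after unwrapping each rotor's phase (removing artificial
#' `2 pi` jumps). The end-to-end difference `phi_{N-1} - phi_0` is the sum
#' of the `chi_n`. Trajectories must resolve individual beats: input
#' sampled more coarsely than 50 samples per period is rejected, since
#' unwrapping is then ambiguous.
#'
#' @param traj A `rotor_trajectory`, or any data frame with a `time` column
#'   and phase columns `phi_0..phi_{N-1}`.
#' @return A tibble of class `chi_series` with columns `time`, `pair`
#'   (zero-based index `n`) and `chi` (rad, continuous). The rotor count and
#'   any trajectory parameters are attached as attributes.
#' @export
phase_differences <- function(traj) {
  phi_cols <- grep("^phi_[0-9]+$", names(traj), value = TRUE)
  N <- length(phi_cols)
  if (N < 2L) stop("need at least two rotors", call. = FALSE)
  phi_cols <- paste0("phi_", seq_len(N) - 1L)
  phi <- as.matrix(traj[phi_cols])
  spp <- apply(phi, 2, samples_per_period)
  if (any(spp < 50))
    stop("trajectory is undersampled (", round(min(spp)),
         " samples per period; need at least 50) - phase unwrapping would be ",
         "ambiguous", call. = FALSE)
  phi_u <- apply(phi, 2, unwrap_phase)
  chi <- phi_u[, -1L, drop = FALSE] - phi_u[, -N, drop = FALSE]
  out <- tibble::tibble(
    time = rep(traj$time, times = N - 1L),
    pair = rep(seq_len(N - 1L) - 1L, each = nrow(phi)),
    chi = as.vector(chi)
  )
  attr(out, "N") <- N
  attr(out, "params") <- attr(traj, "params")
  class(out) <- c("chi_series", class(out))
  out
}

# coerce a trajectory or chi_series to a chi_series
as_chi_series <- function(x) {
  if (inherits(x, "chi_series")) return(x)
  phase_differences(x)
}

# slip events of a single unwrapped series: one event per monotone 2*pi
# excursion from a running reference (hysteresis prevents double counting
# when the series oscillates across a level)
slips_one_series <- function(time, x) {
  times <- numeric(0); dirs <- integer(0)
  ref <- x[1]; i <- 1L; n <- length(x)
  while (i < n) {
    rel <- x[i:n] - ref
    idx <- which(abs(rel) >= 2 * pi)
    if (!length(idx)) break
    j <- i + idx[1] - 1L
    dir <- as.integer(sign(x[j] - ref))
    times <- c(times, time[j]); dirs <- c(dirs, dir)
    ref <- ref + dir * 2 * pi
    i <- j
  }
  list(time = times, direction = dirs)
}

#' Detect phase slips (defects) in neighbor phase differences
#'
#' A slip is a completed monotone `2 pi` excursion of some neighbor phase
#' difference `chi_n`: the local breakdown of frequency locking that
#' appears as a defect in a kymograph and advances the cumulative
#' end-to-end phase difference by one beat. Each `2 pi` crossing of the
#' unwrapped `chi_n` is counted once, with a running-reference hysteresis
#' so that sub-`2 pi` wobbles across a level are not miscounted.
#'
#' @param x A `rotor_trajectory` or a `chi_series` from
#'   [phase_differences()].
#' @return A tibble (event table) with columns `kind` (`"slip"`), `time`
#'   (completion time, s), `pair` (zero-based neighbor index) and
#'   `direction` (+1 if the downstream rotor gained a beat, -1 otherwise).
#'   Zero rows for a fully locked trajectory. The per-pair slip counts are
#'   the slip-position histogram.
#' @export
detect_slips <- function(x) {
  chi <- as_chi_series(x)
  ev <- chi |>
    dplyr::group_by(.data$pair) |>
    dplyr::group_map(function(df, key) {
      s <- slips_one_series(df$time, df$chi)
      if (!length(s$time)) return(NULL)
      tibble::tibble(kind = "slip", time = s$time, pair = key$pair,
                     direction = s$direction)
    }) |>
    dplyr::bind_rows()
  if (!nrow(ev))
    ev <- tibble::tibble(kind = character(0), time = numeric(0),
                         pair = integer(0), direction = integer(0))
  dplyr::arrange(ev, .data$time)
}

#' Detect wobbles in a rotor-chain trajectory
#'
#' A wobble is a transient excursion of the phase profile away from its
#' locked pattern that returns to baseline without completing a `2 pi`
#' slip: soliton-like perturbations that travel along the chain and
#' occasionally terminate in a defect. Detection works on
#' `phi_i - phi_0` relative to a sliding-median baseline (window
#' `baseline_window` mean periods): an event opens when the excursion of
#' the monitored pair exceeds `w_min`, its amplitude `W` is the peak
#' excursion before returning below `w_min / 2`, and the recurrence time
#' `tau` is the separation between successive onsets. `W` can be measured
#' on the initiating pair (`phi_1 - phi_0`) or as the maximal excursion
#' along the chain; the measurement point is reported per event.
#'
#' @param traj A `rotor_trajectory`.
#' @param w_min Minimum excursion amplitude counted as a wobble (rad).
#' @param baseline_window Sliding-median window in mean periods.
#' @param measure `"initiating_pair"` or `"max_along_chain"`.
#' @return A tibble (event table) with columns `kind` (`"wobble"`), `time`
#'   (onset, s), `rotor` (index whose excursion defined `W`), `W` (rad),
#'   `tau` (s, NA for the first event) and `slip_at` (rotor index at which
#'   the wobble terminated in a slip within its excursion window, NA if it
#'   healed).
#' @export
detect_wobbles <- function(traj, w_min = 0.5, baseline_window = 20,
                           measure = c("initiating_pair", "max_along_chain")) {
  measure <- match.arg(measure)
  phi_cols <- grep("^phi_[0-9]+$", names(traj), value = TRUE)
  N <- length(phi_cols)
  if (N < 2L) stop("need at least two rotors", call. = FALSE)
  phi <- apply(as.matrix(traj[paste0("phi_", seq_len(N) - 1L)]), 2,
               unwrap_phase)
  time <- traj$time
  dt <- stats::median(diff(time))
  Tm <- 2 * pi / stats::median(apply(phi, 2, function(x)
    stats::median(diff(x)) / dt))
  k <- max(3L, as.integer(baseline_window * Tm / dt) %/% 2L * 2L + 1L)
  k <- min(k, (length(time) %/% 2L) * 2L - 1L)

  # excursions of phi_i - phi_0 about a slow sliding-median baseline
  exc <- sapply(2:N, function(i) {
    d <- phi[, i] - phi[, 1]
    d - stats::runmed(d, k, endrule = "median")
  })
  exc <- matrix(exc, ncol = N - 1L)

  mon <- abs(exc[, 1])  # initiating pair opens events
  open_idx <- integer(0); events <- list()
  state <- "idle"; start <- NA_integer_
  slips <- detect_slips(traj)
  for (t_i in seq_along(mon)) {
    if (state == "idle" && mon[t_i] >= w_min) {
      state <- "open"; start <- t_i
    } else if (state == "open" && mon[t_i] < w_min / 2) {
      idx <- start:t_i
      if (measure == "initiating_pair") {
        W <- max(mon[idx]); rot <- 1L
      } else {
        peaks <- apply(abs(exc[idx, , drop = FALSE]), 2, max)
        rot <- which.max(peaks); W <- peaks[rot]
      }
      sl <- slips$pair[slips$time >= time[start] & slips$time <= time[t_i]]
      events[[length(events) + 1L]] <- tibble::tibble(
        kind = "wobble", time = time[start], rotor = as.integer(rot),
        W = W, slip_at = if (length(sl)) as.integer(sl[1]) else NA_integer_)
      state <- "idle"
    }
  }
  ev <- dplyr::bind_rows(events)
  if (!nrow(ev))
    return(tibble::tibble(kind = character(0), time = numeric(0),
                          rotor = integer(0), W = numeric(0),
                          tau = numeric(0), slip_at = integer(0)))
  ev$tau <- c(NA_real_, diff(ev$time))
  ev[, c("kind", "time", "rotor", "W", "tau", "slip_at")]
}

#' Complex order parameter of the pairwise phase differences
#'
#' `Z(t) = A e^{i Psi} = (1/(N-1)) sum_{n=0}^{N-2} e^{i chi_n(t)}`, built
#' from the neighbor phase differences rather than the raw phases. A
#' uniform metachronal wave (`chi_n = c` for all `n`) gives `A = 1` and
#' `Psi = c`; a symmetric chevron profile (differences of opposite signs in
#' the two chain halves) gives `Psi = 0`; defect-punctuated dynamics
#' depress `A`. Time averages discard `t <= t_burn`; the average of the
#' angle is circular (argument of the mean unit phasor) and reported as a
#' magnitude.
#'
#' @param traj A `rotor_trajectory` (N >= 2).
#' @param t_burn Burn-in (s) excluded from the averages; defaults to the
#'   trajectory's `t_burn` parameter, or 200 s.
#' @return A tibble of class `order_parameter_series` with columns `time`,
#'   `A` and `Psi`, and attributes `A_bar` and `Psi_bar_abs`.
#' @export
order_parameter <- function(traj, t_burn = NULL) {
  chi <- as_chi_series(traj)
  p <- attr(chi, "params")
  if (is.null(t_burn)) t_burn <- if (!is.null(p)) p$t_burn else 200
  z <- chi |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(z = mean(exp(1i * .data$chi)), .groups = "drop")
  out <- tibble::tibble(time = z$time, A = Mod(z$z), Psi = Arg(z$z))
  sel <- out$time > t_burn
  if (!any(sel)) sel <- rep(TRUE, nrow(out))
  attr(out, "A_bar") <- mean(out$A[sel])
  attr(out, "Psi_bar_abs") <- abs(Arg(mean(exp(1i * out$Psi[sel]))))
  class(out) <- c("order_parameter_series", class(out))
  out
}

#' @export
glance.order_parameter_series <- function(x, ...) {
  tibble::tibble(A_bar = attr(x, "A_bar"), Psi_bar_abs = attr(x, "Psi_bar_abs"))
}

#' End-to-end phase drift per beat
#'
#' Net change of the unwrapped end-to-end phase difference
#' `phi_{N-1} - phi_0` over `(t_burn, t_end)`, in units of beats (divided
#' by `2 pi`), per mean beat of the chain in the same window. Zero for a
#' fully phase-locked run; a chain that slips one beat in every five gives
#' 0.2.
#'
#' @inheritParams order_parameter
#' @return A single number (beats of drift per beat).
#' @export
drift_per_beat <- function(traj, t_burn = NULL) {
  p <- attr(traj, "params")
  if (is.null(t_burn)) t_burn <- if (!is.null(p)) p$t_burn else 200
  phi_cols <- grep("^phi_[0-9]+$", names(traj), value = TRUE)
  N <- length(phi_cols)
  if (N < 2L) stop("need at least two rotors", call. = FALSE)
  phi <- apply(as.matrix(traj[paste0("phi_", seq_len(N) - 1L)]), 2,
               unwrap_phase)
  sel <- traj$time > t_burn
  if (sum(sel) < 2L) stop("no samples after `t_burn`", call. = FALSE)
  phi <- phi[sel, , drop = FALSE]
  adv <- phi[nrow(phi), ] - phi[1, ]
  drift <- adv[[N]] - adv[[1]]
  beats <- mean(adv) / (2 * pi)
  unname((drift / (2 * pi)) / beats)
}

#' End-to-end drift speed
#'
#' Drift rate of the unwrapped end-to-end phase difference over
#' `(t_burn, t_end)` in rad/s. With `method = "net"` this is the raw net
#' change divided by the window; with `method = "quantized"` the net change
#' is first rounded to whole `2 pi` defects, reflecting that end-to-end
#' drift advances through discrete phase slips and that sub-`2 pi`
#' rearrangement of a locked profile is not drift.
#'
#' @inheritParams order_parameter
#' @param method `"net"` or `"quantized"`.
#' @return Drift speed (rad/s).
#' @export
drift_speed <- function(traj, t_burn = NULL, method = c("net", "quantized")) {
  method <- match.arg(method)
  p <- attr(traj, "params")
  if (is.null(t_burn)) t_burn <- if (!is.null(p)) p$t_burn else 200
  phi_cols <- grep("^phi_[0-9]+$", names(traj), value = TRUE)
  N <- length(phi_cols)
  phi <- apply(as.matrix(traj[paste0("phi_", seq_len(N) - 1L)]), 2,
               unwrap_phase)
  sel <- traj$time > t_burn
  tt <- traj$time[sel]
  phi <- phi[sel, , drop = FALSE]
  net <- (phi[nrow(phi), N] - phi[1, N]) - (phi[nrow(phi), 1] - phi[1, 1])
  span <- tt[length(tt)] - tt[1]
  if (method == "quantized") net <- 2 * pi * round(net / (2 * pi))
  unname(net / span)
}

#' Kymograph matrix of a trajectory
#'
#' `sin(phi_i(t))` arranged as a rotor-by-time matrix, the standard visual
#' representation in which metachronal waves appear as diagonal stripes and
#' phase defects as dislocations.
#'
#' @param traj A `rotor_trajectory`.
#' @return A numeric matrix with one row per rotor (rownames `rotor_i`) and
#'   one column per sample; sampling times attached as attribute `"time"`.
#' @export
kymograph <- function(traj) {
  phi_cols <- grep("^phi_[0-9]+$", names(traj), value = TRUE)
  N <- length(phi_cols)
  m <- t(sin(as.matrix(traj[paste0("phi_", seq_len(N) - 1L)])))
  rownames(m) <- paste0("rotor_", seq_len(N) - 1L)
  attr(m, "time") <- traj$time
  m
}
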