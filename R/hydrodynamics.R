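#' Bulk Stokes drag coefficient of a sphere
#'
#' `zeta0 = 6 pi mu a`, the translational drag of a sphere of radius `a` in
#' an unbounded fluid of viscosity `mu`.
#'
#' @param mu Dynamic viscosity (Pa s).
#' @param a Sphere radius (m).
#' @return Drag coefficient (N s/m).
#' @examples
#' bulk_drag(6e-3, 1.74e-6)  # ~1.97e-7 N s/m
#' @export
bulk_drag <- function(mu, a) {
  if (!all(is.finite(mu)) || !all(is.finite(a)) || any(mu <= 0) || any(a <= 0))
    stop("`mu` and `a` must be positive", call. = FALSE)
  6 * pi * mu * a
}

#' Wall-proximity drag correction
#'
#' Dimensionless factor `zetaw(h) = 1 + (9/16) a/h` multiplying the bulk
#' drag of a sphere translating parallel to a plane no-slip wall at height
#' `h` (leading order in `a/h`). It decreases monotonically to 1 as the
#' sphere moves away from the wall.
#'
#' @param a Sphere radius (m).
#' @param h Height of the sphere center above the wall (m); must exceed `a`.
#' @return Dimensionless drag correction, `>= 1`.
#' @examples
#' wall_drag_correction(1.74e-6, 4.2e-6)  # 1.233
#' @export
wall_drag_correction <- function(a, h) {
  if (!all(is.finite(a)) || any(a <= 0))
    stop("`a` must be positive", call. = FALSE)
  if (!all(is.finite(h)) || any(h <= a))
    stop("invalid geometry: height `h` must exceed the bead radius `a`",
         call. = FALSE)
  1 + (9 / 16) * a / h
}

#' Free-space Oseen tensor
#'
#' The Green's function of Stokes flow in an unbounded fluid:
#' `S_ij(r) = (delta_ij / |r| + r_i r_j / |r|^3) / (8 pi mu)`. It is the
#' limit of the wall Green's function when both points are far from the
#' wall compared to their separation.
#'
#' @param r Separation vector (length-3 numeric, m), target minus source.
#' @param mu Dynamic viscosity (Pa s).
#' @return A 3x3 mobility tensor (m / (N s)).
#' @export
oseen_tensor <- function(r, mu) {
  r <- as.numeric(r)
  if (length(r) != 3L || !all(is.finite(r)))
    stop("`r` must be a finite length-3 vector", call. = FALSE)
  rn <- sqrt(sum(r^2))
  if (rn == 0) stop("coincident points: |r| must be > 0", call. = FALSE)
  (diag(3) / rn + tcrossprod(r) / rn^3) / (8 * pi * mu)
}

#' Green's function of Stokes flow above a plane no-slip wall
#'
#' Velocity response at `target` per unit point force at `source`, for a
#' fluid bounded below by a rigid no-slip plane at zero height. The tensor
#' is the free-space Stokeslet plus Blake's image system (image Stokeslet,
#' Stokeslet doublet and source doublet placed at the mirror point), which
#' makes the velocity vanish identically on the wall. Wall-parallel
#' couplings decay with lateral distance `r` as `1/r` when `r` is small
#' compared to the heights and as `1/r^3` when `r` is large: the wall
#' screens distant interactions, which is what changes the character of the
#' chain dynamics as rotors approach it.
#'
#' Coordinates: the wall is the plane of zero third component; both points
#' must have strictly positive height.
#'
#' @param source Position of the point force (length-3, m).
#' @param target Position where the velocity is evaluated (length-3, m).
#'   May lie on the wall (height 0), where the returned tensor is zero.
#' @param mu Dynamic viscosity (Pa s).
#' @return A 3x3 mobility tensor `G` (m / (N s)) such that `u = G %*% F`.
#' @examples
#' G <- blake_tensor(c(0, 0, 5e-6), c(9.19e-6, 0, 5e-6), mu = 6e-3)
#' @export
blake_tensor <- function(source, target, mu) {
  source <- as.numeric(source); target <- as.numeric(target)
  if (length(source) != 3L || length(target) != 3L ||
      !all(is.finite(c(source, target))))
    stop("`source` and `target` must be finite length-3 vectors", call. = FALSE)
  if (source[3] <= 0)
    stop("source must lie strictly above the wall", call. = FALSE)
  if (target[3] < 0)
    stop("target must not lie below the wall", call. = FALSE)
  if (all(source == target))
    stop("coincident points: source and target must differ", call. = FALSE)

  hs <- source[3]
  r <- target - source
  R <- c(r[1], r[2], target[3] + source[3])  # target minus image point
  rn <- sqrt(sum(r^2)); Rn <- sqrt(sum(R^2))

  stokeslet <- function(v, vn) diag(3) / vn + tcrossprod(v) / vn^3
  # Dmat[i, l] = d/dR_l [ hs R_i/R^3 - delta_i3/R - R_i R_3/R^3 ]
  I3 <- diag(3)
  Dmat <- hs * (I3 / Rn^3 - 3 * tcrossprod(R) / Rn^5) -
    (I3 * R[3] + outer(R, c(0, 0, 1))) / Rn^3 +
    outer(c(0, 0, 1), R) / Rn^3 +
    3 * R[3] * tcrossprod(R) / Rn^5
  M <- c(1, 1, -1)  # image force parity: wall-parallel vs wall-normal
  G <- stokeslet(r, rn) - stokeslet(R, Rn) +
    2 * hs * sweep(Dmat, 2, M, `*`)
  G / (8 * pi * mu)
}

#' Bead velocities from external forces near a wall
#'
#' Far-field mobility relation for a collection of beads above a no-slip
#' wall: each bead advects with its own force through the wall-corrected
#' Stokes drag, plus the flow generated at its position by every other
#' bead's force through the wall Green's function,
#' `v_i = F_i / (zeta0 zetaw(h_i)) + sum_{j != i} G(x_j, x_i) F_j`.
#' Beads enter the coupling as point forces; finite size enters only
#' through the self-drag. With `truncation = "nearest_neighbor"` the
#' coupling sum keeps only `|i - j| = 1` (rows are taken as chain order).
#'
#' @param positions Bead positions: an N x 3 matrix or a data frame with
#'   three columns (m); heights (third column) must exceed `a`.
#' @param forces External forces, same shape as `positions` (N).
#' @param mu Dynamic viscosity (Pa s).
#' @param a Bead radius (m).
#' @param truncation `"none"` or `"nearest_neighbor"`.
#' @return A tibble with columns `vx`, `vy`, `vz` (m/s), one row per bead.
#' @examples
#' pos <- rbind(c(0, 0, 5e-6), c(9.19e-6, 0, 5e-6))
#' f <- rbind(c(0, 1e-12, 0), c(0, 1e-12, 0))
#' mobility_velocities(pos, f, mu = 6e-3, a = 1.74e-6)
#' @export
mobility_velocities <- function(positions, forces, mu, a,
                                truncation = c("none", "nearest_neighbor")) {
  truncation <- match.arg(truncation)
  positions <- as.matrix(positions); forces <- as.matrix(forces)
  if (ncol(positions) != 3L || ncol(forces) != 3L ||
      nrow(positions) != nrow(forces))
    stop("`positions` and `forces` must be N x 3 with equal N", call. = FALSE)
  n <- nrow(positions)
  if (any(positions[, 3] <= 0))
    stop("all positions must lie strictly above the wall", call. = FALSE)
  if (n > 1) {
    d2 <- as.matrix(stats::dist(positions))^2
    if (any(d2[upper.tri(d2)] == 0))
      stop("overlapping positions", call. = FALSE)
  }
  v <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    zw <- wall_drag_correction(a, positions[i, 3])
    v[i, ] <- forces[i, ] / (bulk_drag(mu, a) * zw)
    for (j in seq_len(n)) {
      if (j == i) next
      if (truncation == "nearest_neighbor" && abs(i - j) != 1L) next
      v[i, ] <- v[i, ] +
        blake_tensor(positions[j, ], positions[i, ], mu) %*% forces[j, ]
    }
  }
  tibble::tibble(vx = v[, 1], vy = v[, 2], vz = v[, 3])
}
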