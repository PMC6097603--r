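---
title: "Model cilia as driven rotors above a wall: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model cilia as driven rotors above a wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotorwave)
```

## The physical model

`rotorwave` simulates a minimal model of a ciliated surface: a linear chain
of `N` micron-scale beads, each driven around a circular orbit of radius
`R` in a plane a distance `h` above a rigid no-slip wall, with orbit
centers spaced `ell` apart along one wall-parallel axis. Bead `i`
(zero-based) feels

* a constant tangential driving force of magnitude
  `F_i = F_dr * D^(i - 0.5)`, so a detuning `D > 1` imposes a geometric
  ladder of intrinsic frequencies along the chain (across six rotors at
  `D = 1.01` the spread is `D^5 = 1.051`, about 5%), and
* a radial harmonic restoring force `-lambda (rho_i - R)` that makes the
  orbit compliant. This compliance is the mechanism of synchronization:
  a neighbor's flow can push a bead slightly off its orbit, which changes
  its angular speed and lets phases adjust. Rigid orbits
  (`lambda -> Inf`) cannot synchronize this way.

At these scales inertia is irrelevant (Reynolds number ~1e-5), so bead
velocities follow from an instantaneous mobility relation: each bead moves
with its own force through the wall-corrected Stokes drag
`zeta0 * zetaw(h)` (`zeta0 = 6 pi mu a`, `zetaw = 1 + (9/16) a/h`), and is
advected by the flow the other beads' forces create. That flow is the
Green's function of Stokes flow bounded by a plane no-slip wall: a
Stokeslet plus its image system (image Stokeslet, Stokeslet doublet and
source doublet at the mirror point). The wall qualitatively changes the
range of the interaction: wall-parallel disturbances decay as `1/r` far
from the wall (`beta = 2h/ell >> 1`) but as `1/r^3` near it
(`beta << 1`). Raising the chain therefore strengthens *all* couplings
while shifting relative weight from nearest neighbors to long range --
that competition is what the package exists to study.

Key modelling assumptions, all deliberate:

* **Far-field point coupling.** Beads enter the interaction as point
  forces; finite size appears only in the self-drag. At `a/ell = 0.19`
  this is a leading-order description.
* **Planar confinement.** The traps prescribe a planar array of circles,
  so the state per rotor is `(phi_i, rho_i)` and wall-normal velocity
  components are discarded. No vertical trap dynamics are modelled.
* **Deterministic dynamics.** Thermal fluctuations are excluded by
  design; every run is exactly reproducible from its parameters and
  initial phases.
* **Instantaneous traps.** Feedback delay in a real optical-tweezer
  implementation effectively softens the traps; it is represented by a
  single multiplicative factor `gamma = 2.21` applied to `lambda` when a
  configuration is declared as experimentally calibrated
  (`experimental_lambda = TRUE`), not by delay equations.

## Parameters

| name | meaning | default | unit |
|---|---|---|---|
| `a` | bead radius | 1.74e-6 | m |
| `R` | orbit radius | 1.59e-6 | m |
| `ell` | center spacing | 9.19e-6 | m |
| `h` | height above wall | 11.7e-6 | m |
| `mu` | viscosity | 6e-3 | Pa s |
| `lambda` | radial stiffness | 2.06e-6 | N/m |
| `F_dr` | drive scale | 2.23e-12 | N |
| `D` | detuning | 1.01 | - |
| `N` | rotors | 6 | - |
| `t_end` | horizon | 2000 | s |
| `t_burn` | burn-in for averages | 200 | s |

The defaults are the bead-array values of the experimental system this
model idealizes; with them an isolated rotor far from the wall beats with
a period of about 0.88 s, and the wall slows it by exactly `zetaw`.
`lambda` of a few pN/um corresponds to the bending stiffness of a
flagellum of typical length (`lambda ~ kappa / L^3`), which is why the
sweeps span 1-10 pN/um.

## Averaged pair theory

For two rotors the slow dynamics of the phase difference
`chi = phi_1 - phi_0` averages, over the fast rotation, to

```
chi_dot = (F_1 - F_0) / (R zeta0 zetaw)
          - (3a / 4 ell) (F_0 F_1 / (lambda zeta0 R^2)) [2A(beta) + B(beta)] sin(chi)
```

with `X = 1/sqrt(1 + beta^2)`, `A = 1 - X - (beta^2/2) X^3`,
`B = 1 - X^3 + (3 beta^2/2) X^5`. (The orbit-radius symbol in the
averaged equation is identified with the trap radius `R`; the package uses
a single radius throughout.) This is an Adler equation: locking survives
while the detuning term does not exceed the coupling amplitude, and beyond
the saddle-node the time-averaged drift is
`sqrt(detuning^2 - coupling^2)`, growing as the square root of the excess.
On the locked branch `average_drift()` returns exactly zero rather than a
complex root. Setting detuning equal to coupling and using the geometric
force ladder gives the boundary in closed form:
`sqrt(D) - 1/sqrt(D) = C`, so `D* = ((C + sqrt(C^2 + 4))/2)^2` with
`C = (3a/4ell)(F_dr zetaw / (lambda R))(2A + B)`. `D*(h)` increases with
height because `2A + B` grows toward its bulk value 3.

```{r pair-theory}
p <- rotor_params(N = 2)
critical_detuning(p, h = c(4.2e-6, 11.7e-6, 51.7e-6))
```

The same coupling amplitude evaluated at separations `n * ell` and
normalized over the first five neighbors gives the height-dependent
neighbor-coupling profile; its `beta -> 0` and `beta -> Inf` limits are the
pure power-law fractions `S(n) = n^-j / sum(i^-j)` with `j = 3` and
`j = 1` (`S(1) = 0.84` and `0.44`).

## Numerical choices

* **Integrator.** `deSolve::ode` (`lsoda`) over a compiled right-hand
  side, `rtol = 1e-8`, `atol = 1e-10`. A pure-R implementation of the same
  equations (`rotor_rhs()`) is kept as a readable reference and
  cross-checked against the compiled path in the tests; tightening the
  tolerances tenfold changes measured drift by well under 1%.
* **Sampling.** Output on a uniform grid of 100 samples per *intrinsic*
  mean period. The coupled chain can rotate up to ~30% faster than the
  intrinsic estimate (neighboring flows advect each bead forward), so the
  margin keeps the realized sampling far above the 50-samples-per-beat
  floor that the unwrapping step enforces; coarser input is rejected as
  undersampled rather than silently misread.
* **Initial conditions.** `rho_i = R` exactly; `phi_i` uniform on
  `[0, 2 pi)` from a stored integer seed. Sweep cell `k` uses
  `master_seed + k`, so any cell reproduces in isolation.
* **Slip detection.** One event per completed monotone `2 pi` excursion
  of an unwrapped neighbor difference, tracked against a running reference
  (hysteresis). This cannot double-count a sub-`2 pi` wobble that
  oscillates across a level, and it makes slip counts consistent with net
  drift to within one slip per pair by construction.
* **Wobble detection.** Excursions of `phi_i - phi_0` about a sliding
  median baseline (window 20 mean periods, `stats::runmed`); an event
  needs amplitude `W >= 0.5` rad (configurable -- observed wobbles are of
  order 1-2 rad) and must return below half the threshold. `W` can be
  measured on the initiating pair or as the maximum along the chain; the
  choice is reported per event. A wobble that brackets a detected slip is
  marked as having terminated in a defect at that rotor.
* **Order parameter.** `Z = (1/(N-1)) sum_{n=0}^{N-2} exp(i chi_n)` over
  the `N - 1` pairwise differences. The angle average is circular (the
  argument of the mean unit phasor), since `Psi` is an angle.
* **Classification.** A cell is `defect` if `|drift per beat| > 1e-3`,
  else `chevron` if `|Psi_bar| < 0.05` rad, else `mw`. Thresholds are
  arguments, not constants.
* **End-to-end drift speed.** Reported either as the raw net slope or
  quantized to whole `2 pi` defects. The quantized form is the right
  yardstick for height-insensitivity comparisons of locked or nearly
  locked chains, where a sub-`2 pi` rearrangement of the locked profile
  between the window's endpoints is not drift.

## Design choices where the design was open

* **Pair-drift validation point.** The full two-rotor simulation is
  compared with the averaged closed form at `D = 1.25`, well above
  `D* = 1.135` at `h = 4.2` um. Near the saddle-node the comparison is
  dominated by the averaging theory's own boundary shift (the simulated
  boundary sits slightly above the theoretical one, and the package
  reproduces that ordering); away from it the two agree to a few percent.
* **Drift-peak estimate.** The end-to-end drift per beat at
  `lambda = 4.5` pN/um, `h = 50` um depends on the random initial phases;
  the reported value is the mean over three realizations (about
  0.15-0.16 beats per beat, i.e. the chain loses roughly one beat in six
  to seven at this point of parameter space, against roughly one in five
  for the experiment-matched reference).
* **Locked-state threshold.** An experimental classification of
  drift-versus-lock by "five slips per experiment" corresponds to
  different drift rates for different observation times, so the slip
  threshold in `pair_bifurcation_scan()` is an argument (default 5 per
  run) rather than a hard-coded rate.
* **Problem sizes.** Chain analyses use `N = 6` and `t_end = 2000` s with
  averages over `t > 200` s; pair validations use 150-400 s horizons,
  which hold the drift-rate estimates to well under the tolerances being
  tested. The default sweep grid is 8 x 8 (heights log-spaced 5-1000 um,
  stiffness 1-10 pN/um); denser grids are a config choice.

## What the simulations do and do not show

Everything here is deterministic and far-field. The package reproduces
the model-side phenomenology: robust pair synchronization that
strengthens with height; a metachronal wave at small `h` driven by the
detuning bias; wobbles and phase defects at intermediate and large `h`;
chevron profiles at low stiffness; near-complete height insensitivity
when coupling is truncated to nearest neighbors. It does not attempt to
reproduce noisy experimental observables: thermal fluctuations, trap
feedback delay beyond the static `gamma` factor, finite-bead-size
corrections to the coupling, and image-based phase extraction are all
absent, so quantities tied to those (e.g. measured wobble statistics of a
noisy run) should be compared only qualitatively. Within the model,
transient radial excursions during defects can reach 10-25% of `R` at
large heights -- compliance is a perturbation on average, not uniformly.
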