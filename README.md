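# rotorwave

Deterministic simulation and analysis of hydrodynamically coupled
colloidal rotors above a no-slip wall — a minimal model for how chains of
cilia coordinate into metachronal waves, and how that coordination breaks.

## The problem

Eukaryotic cilia beat in coordinated traveling waves. A productive minimal
model replaces each cilium with a micron-sized bead driven around a
compliant circular orbit (radius *R*, radial stiffness *λ*) at height *h*
above a rigid wall, with the *i*-th of *N* rotors driven by a constant
tangential force *F<sub>i</sub> = F<sub>dr</sub> D<sup>i−0.5</sup>* (a
geometric detuning ladder, *D* = 1.01 by default). The only communication
between rotors is hydrodynamic: at zero Reynolds number each bead is
advected by the flows of all the others,

&nbsp;&nbsp;*v<sub>i</sub>* = *F<sub>i</sub>* / (ζ<sub>0</sub>ζ<sub>w</sub>) + Σ<sub>j≠i</sub> **G**(x<sub>j</sub>, x<sub>i</sub>) · *F<sub>j</sub>*,

where ζ<sub>0</sub> = 6πμa, ζ<sub>w</sub> = 1 + (9/16)(a/h), and **G** is
the Green's function of Stokes flow above a plane no-slip wall (Stokeslet
plus image system). The wall screens the coupling — wall-parallel flows
decay as 1/r³ near the wall but 1/r far from it — so the height *h* tunes
the *range* of the interaction. Near the wall the chain locks into a
metachronal wave; far from it, long-range coupling destabilizes the wave
into chevron profiles or phase-lock punctuated by periodic phase defects
(2π slips), even though any isolated *pair* of rotors only synchronizes
more robustly with height.

The package provides:

* `blake_tensor()`, `mobility_velocities()` — wall Green's function and
  far-field mobility relations;
* `simulate_rotors()` — adaptive integration of the N-rotor chain
  (compiled right-hand side, `deSolve`), returning a tidy trajectory;
* `adler_rhs()`, `average_drift()`, `critical_detuning()`,
  `pair_bifurcation_scan()`, `coupling_fraction()`,
  `neighbor_coupling_profile()` — the averaged two-rotor phase theory,
  its saddle-node synchronization boundary *D\*(h)*, and
  neighbor-coupling fractions;
* `phase_differences()`, `detect_slips()`, `detect_wobbles()`,
  `order_parameter()`, `drift_per_beat()`, `kymograph()` — trajectory
  diagnostics (slips, wobbles with amplitude *W* and recurrence τ, the
  complex order parameter *Z = A e<sup>iΨ</sup>* of pairwise phase
  differences);
* `run_sweep()`, `classify_cell()` — (h, λ) phase-diagram sweeps with
  optional nearest-neighbor truncation of the coupling;
* `autoplot()` methods, `tidy()`/`glance()` views, CSV/JSON trajectory
  I/O, and a command-line driver (`exec/rotorwave`).

## Worked example

Simulate the six-rotor chain high above the wall at the stiffness where
defects are most frequent, and summarize it:

```r
library(rotorwave)

p <- rotor_params(N = 6, h = 50e-6, lambda = 4.5e-6, t_end = 600, t_burn = 200)
traj <- simulate_rotors(p)
glance(traj)
#> # A tibble: 1 × 6
#>       N t_end drift_per_beat A_bar Psi_bar_abs n_slips
#>   <int> <dbl>          <dbl> <dbl>       <dbl>   <int>
#> 1     6   600          0.173 0.680       0.353     148
```

The chain is not phase-locked: the rotors at opposite ends drift apart by
about 0.17 beats per beat (roughly one slip every six beats), the
order-parameter amplitude Ā ≈ 0.68 reflects a wave repeatedly disrupted
by defects, and 148 individual 2π slips were detected. The defects
cluster in the interior of the chain:

```r
table(detect_slips(traj)$pair)
#>   1   2   3
#>   5 136   7
```

By contrast the averaged pair theory shows why any single pair stays
locked here: the critical detuning exceeds D = 1.01 at every
experimental height, and grows with h,

```r
critical_detuning(rotor_params(N = 2), h = c(4.2e-6, 51.7e-6))
#> [1] 1.134626 1.308210
```

while the coupling budget shifts away from nearest neighbors as the wall
recedes — near the wall the first neighbor carries 84% of it:

```r
round(coupling_fraction(1:5, j = 3), 3)
#> [1] 0.843 0.105 0.031 0.013 0.007
```

`autoplot(traj)` draws the kymograph (sin φ<sub>i</sub> over rotor and
time); `autoplot(run_sweep(...))` maps drift, Ā, |Ψ̄| or the regime label
over an (h, λ) grid.

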