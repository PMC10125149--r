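---
title: "Modelling miniprotein dwell times and occupied-pore currents in a solid-state nanopore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling miniprotein dwell times and occupied-pore currents in a solid-state nanopore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(porepass)
library(ggplot2)
```

## The problem

A solid-state nanopore senses single molecules through two observables: how
much the analyte attenuates the voltage-driven ionic current while it
occupies the pore, and how long it stays there (the dwell or translocation
time). For small, similarly sized miniproteins the occupied-pore current
magnitudes can be nearly indistinguishable, so the dwell time carries the
discriminating signal. Simulating full translocation events with molecular
dynamics is prohibitively expensive at the microsecond scales involved;
`porepass` instead implements a kinetic model that predicts dwell times from
*static* ingredients — per-amino-acid pore-wall interaction energies, the
protein's surface geometry and charge — plus the standard analysis chain for
occupied-pore currents computed from ion trajectories.

## The dwell-time model

The analyte is treated as hopping between two states: bound at the pore wall
at its equilibrium separation, and free at large separation. With the
protein-level interaction energy $\Delta E_\mathrm{protein}$ (negative for
attraction) the dwell time follows a Boltzmann ratio,

$$\tau \;=\; \tau_0 \, e^{-\beta\, \Delta E_\mathrm{protein}},$$

so $\tau(0) = \tau_0$ exactly, attraction lengthens the dwell and repulsion
shortens it.

Two quantities close the model:

* **The transition energy scale** $\beta^{-1}$. The energy available to pull
  a charged analyte off the wall is the electrostatic work across the
  membrane, so $\beta^{-1} = |q| \cdot V$ in eV — 1 eV for a +1e analyte at
  1 V, 2 eV for a −2e analyte. The linear rule extrapolates to other
  voltages; for an uncharged analyte the electrophoretic picture breaks down
  and `beta_inv` must be supplied explicitly.
* **The noninteracting transit time** $\tau_0$. A protein of mass $m$ and
  charge $q$ entering the pore feels a uniform electrostatic force
  $qE = qV/h$ (field = bias over membrane thickness $h$) and a linear drag
  $-\gamma v$. `solve_tau0()` integrates $m\dot v = qE - \gamma v$ and
  returns the first time the analyte has covered the traversal length,
  cross-validating the stiff numerical solution against the closed form
  $x(t) = v_\infty t - (v_\infty - v_0)(m/\gamma)(1 - e^{-\gamma t/m})$ to
  better than $10^{-8}$ relative. By default $\gamma$ is calibrated from the
  observed drift-speed scale of the analyte, $\gamma = |q|E/v_\infty$ with
  $v_\infty = 0.1$ m/s, which reproduces that speed without guessing a
  hydrodynamic radius; a Stokes-style `drag_coefficient` can be supplied
  instead. At the defaults (38 Å membrane, 0.1 m/s) the transit is
  overdamped — inertia relaxes in femtoseconds — and $\tau_0 \approx L /
  v_\infty = 38$ ns.

```{r kinetics}
protein <- gen_toy_protein(4, codes = rep("GLY", 4), rsa = rep(0.5, 4),
                           geometry = "line", net_charge = 1, mass_kda = 3.9)
tau0 <- solve_tau0(protein, kinetics_config(bias_voltage = 1.0))
c(tau0_ns = as.numeric(tau0) * 1e9,
  rel_err_vs_closed_form = abs(as.numeric(tau0) - attr(tau0, "closed_form")) /
    attr(tau0, "closed_form"))
```

Dwell estimates are reported at the mean interaction energy and at mean ±
one standard deviation of the energy distribution; two analytes are called
*separable* when those closed ranges are disjoint. The one-standard-deviation
convention for the range is a package choice — the width of the reported
band should be read with that in mind.

## Per-amino-acid interaction energies

The input for one residue type is an energy scan: the total energy of the
amino-acid/pore-wall system over increasing separations (fine 0.1–0.2 Å
steps near contact, 1 Å steps out to ~15 Å). Two numbers are extracted:

* **Equilibrium energy** $E_\mathrm{eq}$: the minimum of a quadratic-spline
  interpolant through the points. If the interpolated vertex evaluates above
  the lowest computed point — sharp wells can defeat the interpolant — the
  lowest computed value is used instead and the result is flagged
  `lowest_point`; a minimum at the scan boundary falls back the same way
  with a warning, never silently.
* **Asymptotic energy** $E_\mathrm{asymp}$: the plateau $C + D$ of a Morse
  fit $V(s) = C + D(1 - e^{-a(s-s_0)})^2$ over all points, which pins the
  large-separation limit far more stably than the last few samples alone.

The interaction energy is $\Delta E^{AA} = E_\mathrm{eq} - E_\mathrm{asymp}$,
invariant under any additive offset of the scan. The packaged table ships
the 18 residue types with derived energies (all attractive, stored signed);
lookups of the two absent residues (MET, ILE) are an error unless an
explicit substitute mapping is given — the package never invents an energy.

```{r curve}
curve <- gen_energy_curve(D = 1.0, a = 1.2, s0 = 2.5, C = -3.0)
interaction_energy(curve)
autoplot(curve, fit = fit_morse(curve))
```

## From residues to the protein: the selection model

Only a bounded contact patch of residues can sit at the wall's equilibrium
distance simultaneously; the default patch size is $N = 4$ (configurable
downward — the bound is treated as the operating value). A patch is drawn in
two stages:

1. the seed residue, with probability proportional to its relative surface
   accessibility (RSA) — buried residues cannot touch the wall;
2. the remaining $N - 1$ residues uniformly *without replacement* from the
   seed's $L = 5$ geometrically nearest neighbours (a physical patch cannot
   contain a residue twice, and the seed is excluded from its own pool).

Patch energies add linearly over the member residues. Repeating the draw
(500 000 times by default) yields the protein-level energy distribution,
summarised by its signed mean and standard deviation and fitted with a
zero-location gamma distribution. The gamma is fitted to the *magnitudes*
$|\Delta E_\mathrm{protein}|$ — the samples are all negative for an
all-attractive table, and fitting magnitudes keeps the support positive
where a gamma lives; maximum likelihood is used with a method-of-moments
fallback, and degenerate samples (one rep, or zero spread) skip the fit with
a flag.

`enumerate_exact()` computes the same law exactly — every seed crossed with
every neighbour subset — and is the package's independent oracle for the
sampler. Geometric distance uses the alpha-carbon as each residue's
representative point (configurable to the side-chain centroid); exact
distance ties break to the lower residue index, compared at 12 significant
digits so ties arising from floating-point construction still break
deterministically.

```{r selection}
set.seed(42)
codes <- c("CYS", "GLY", "ALA", "SER", "THR", "VAL", "LEU", "PHE")
toy <- gen_toy_protein(8, codes = codes, rsa = runif(8, 0.05, 0.95),
                       geometry = "random", seed = 42)
nb <- neighbors(toy, L = 5)
dist <- sample_energy_distribution(toy, nb, aa_energy_table(),
                                   selection_config(reps = 50000, seed = 1))
glance(dist)
enumerate_exact(toy, nb, aa_energy_table())
```

RSA values are, by design, *user-supplied* (the kind of per-residue
accessibility a structure-based predictor emits); `compute_rsa()` offers an
offline Shrake–Rupley computation — deterministic Fibonacci-lattice point
sampling, 1.4 Å probe, normalised by a published theoretical maximum-ASA
set and clipped at 1 — but it is never a silent fallback. RSA is treated as
static for a given structure; tracking its time evolution along a
trajectory is out of scope.

## Occupied-pore current analysis

The current while the pore is occupied is computed from ion trajectories as
the charge-weighted sum of axial displacements inside the pore region,

$$I(t) = \frac{1}{\delta t \; l_z} \sum_i q_i \,
  \big[z_i(t + \delta t) - z_i(t)\big],$$

with $l_z = 36$ Å, $\delta t$ the frame spacing (1 ps in the intended
inputs) and 1 e/ps = 160.2177 nA. Slab membership ($|z - z_c| < l_z/2$,
strict at the faces) is judged at the earlier frame of each displacement
pair; ions that disappear between frames are skipped with a counted
warning. When the trajectory comes from a periodic box the analyzer
minimum-images each displacement, so wrapped coordinates yield physical
displacements — the single most error-prone piece of plumbing in this
chain, and the reason the synthetic generator records its box height.

Traces are smoothed with a zero-phase low-pass filter: a 4th-order
Butterworth applied forward and backward (design and order are package
choices — only the cutoffs, 5 GHz for current histograms and 1 GHz for
smoothing tracks, are externally meaningful). The series mean is removed
before filtering and restored after, so the DC component survives exactly,
and odd-reflection padding suppresses edge transients; two passes square
the magnitude response, putting the gain at the cutoff at exactly 1/2.
Histograms support time-window exclusion masks (for frames where the
analyte escaped or unfolded), and can be conditioned on whether the
analyte's dipole moment was aligned with the field axis — "aligned" means
within 90° of the axis by default, i.e. the sign of the axial dipole
component.

```{r current}
ions <- gen_ion_trajectory(n_ions = 20, drift = 2.5, diffusion = 2,
                           frames = 300, seed = 7)
trace <- instantaneous_current(ions)
smooth <- lowpass(trace, filter_spec(5))
c(mean_current_na = mean(trace$current),
  expected_na = attr(ions, "truth")$expected_current_na)
autoplot(smooth)
```

## What the synthetic generators emulate — and what they do not

The three generators replace the expensive upstream physics so the whole
pipeline runs from code:

* `gen_energy_curve()` emulates a separation scan with a Morse-shaped truth
  and optional Gaussian noise, on the fine-near/coarse-far grid scheme real
  scans use. It does not emulate systematic errors (basis-set effects,
  missing solvent) that shift real total energies non-randomly.
* `gen_toy_protein()` provides line/ring/random residue geometries with
  pass-through RSA. It makes no claim to realistic folds.
* `gen_ion_trajectory()` produces field-driven drift-diffusion ions in a
  periodic box with charge-antisymmetric drift, at magnitudes chosen to give
  roughly ten pore ions and currents of order 100 nA. Ion–ion correlations,
  water and access resistance are absent.

Passing tests on these fixtures therefore demonstrate the *estimators and
the model algebra* are correct (unbiasedness of the current estimator,
sampler-versus-enumeration equivalence, filter contracts, transit-time
closed forms) — not that the physical inputs themselves are accurate. With
real scans, structures and RSA tables the same code paths apply unchanged.

## Numerical choices

* **Quadratic spline**: knot slopes are taken from the centred three-point
  Lagrange parabola at each knot (one-sided at the ends), each piece then
  interpolating its two endpoints. This keeps the interpolant local and
  stable — the classical chained continuous-derivative construction
  propagates an oscillating error term that inflates the vertex — and it
  reproduces a globally quadratic curve exactly. Minima are located by
  per-piece vertex evaluation plus the sampled-point check. Vertex-value
  accuracy scales as the fourth power of the local spacing: at 0.1 Å
  spacing a 1 eV Morse well is recovered to ~2×10⁻⁴ eV, at 0.02 Å to
  ~3×10⁻⁷ eV; the exactness checks in the tests use the finer grid for this
  reason and the generator's default grid retains the realistic 0.1 Å
  spacing.
* **Morse fitting**: Levenberg–Marquardt with analytic-free bounds
  ($D, a > 0$), starts at plateau-minus-minimum depth and the sampled
  minimum, plus up to 10 deterministically jittered restarts (fixed internal
  seed; the global RNG state is untouched). Non-convergence raises a
  fit-failure error carrying residuals.
* **Sampling**: a uniform draw of an $(N-1)$-subset without replacement is
  implemented as a uniform index into the enumerated subsets of the
  neighbour pool (identical law, fully vectorised); the per-draw path is
  kept for pool sizes whose subset count exceeds 5000. Fixed seeds make the
  sample stream bit-reproducible.
* **Transit-time integration**: the ODE is nondimensionalised on the
  closed-form answer and solved with a stiff solver with root detection
  (relative tolerance 10⁻¹²), so the femtosecond relaxation inside a
  nanosecond transit costs nothing in accuracy.
* **Degenerate inputs**: all-zero RSA falls back to uniform weights with a
  warning; a boundary scan minimum falls back to the lowest computed value
  with a warning; exponents beyond ±700 in the dwell exponential return
  `Inf` with an `overflow` flag rather than NaN.

## Problem sizes in the test-suite and reproduction script

The shipped tests run the sampler at up to 5×10⁵ repetitions on 6–8-residue
toys (where exact enumeration is cheap), drift-diffusion fixtures at 20–40
ions × 300–500 frames, filter contracts on 2×10⁴-sample traces, and
replicate studies of Monte-Carlo scatter at 10³–10⁵ repetitions × 100–200
seeds — sizes chosen so every check has comfortable statistical margin while
the whole suite completes in about a minute.

## Limitations

* Thermal fluctuations of the interaction energies are not modelled; the
  energy distribution reflects patch combinatorics only.
* Electroosmotic and electrophoretic solvent flow, entropic barriers,
  conformational deformation and unfolding are outside the kinetic model.
* $\beta^{-1} = |q|V$ is a linear electrophoretic estimate; at voltages far
  from the calibration regime, or for nearly neutral analytes, it should be
  overridden.
* The dwell "range" is a ±1σ energy band, not a confidence interval over
  translocation events.
* The current analyzer assumes monovalent ions and a z-defined pore region
  (no radial membership test).
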