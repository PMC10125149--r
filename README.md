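# porepass

Dwell-time and occupied-pore current modelling for solid-state nanopore
sensing of miniproteins.

## What it does and for whom

Solid-state nanopores identify single molecules by how much an analyte
attenuates the pore's ionic current and how long it dwells inside. For
similar miniproteins the current magnitudes alone often cannot tell them
apart, but their dwell times can. `porepass` is for computational
biophysicists who want to *predict* whether two candidate proteins are
distinguishable — without simulating full translocation events, which is far
beyond routine molecular-dynamics budgets.

The core model treats translocation as a Boltzmann transition between a
wall-bound and a free state:

    tau = tau0 * exp(-beta * dE_protein)

* `dE_protein` — protein-level pore-wall interaction energy, built by a
  combinatorial selection model: a contact patch of N = 4 residues, seeded
  by a relative-surface-accessibility (RSA) weighted draw and completed
  uniformly from the seed's L = 5 nearest neighbours; patch energies add
  linearly from a per-residue energy table. Repeated 500 000 times this
  yields an energy distribution with a gamma fit; an exact enumeration
  oracle validates the sampler.
* Per-residue energies come from energy-versus-separation scans:
  equilibrium point by quadratic-spline interpolation (falling back to the
  lowest computed value when the interpolant cannot beat it), asymptote by a
  Morse-potential fit `V(s) = C + D (1 - exp(-a (s - s0)))^2`, and
  `dE_AA = E_eq - E_asymp`. A packaged 18-residue table ships with the
  package.
* `beta^-1 = |q| V` (eV) — the electrostatic work available across the
  membrane for an analyte of net charge q at bias V.
* `tau0` — the noninteracting transit time, solved from
  `m dv/dt = qE - gamma v` over the 38 Å membrane and cross-checked against
  its closed form.

Alongside the kinetics, the package implements the occupied-pore current
analysis chain used on ion trajectories:
`I(t) = (1/(dt*lz)) * sum_i q_i [z_i(t+dt) - z_i(t)]` over the 36 Å pore
slab (1 e/ps = 160.2177 nA), per-frame pore ion counts, zero-phase
Butterworth low-pass filtering, current histograms with exclusion masks,
center-of-mass tracking and dipole-alignment conditioning. Seeded synthetic
generators (Morse-shaped scans, toy proteins, drift-diffusion ion
trajectories with known expected current) let the full pipeline run with no
external simulation data.

## Worked example

Two 8-residue toy proteins with the packaged energy table — one +1e /
3.9 kDa, one −2e / 3.6 kDa — through the full pipeline at 1 V:

```r
library(porepass)
tab <- aa_energy_table()
set.seed(42)
a <- gen_toy_protein(8, c("CYS","GLY","ALA","SER","THR","VAL","LEU","PHE"),
                     runif(8, 0.05, 0.95), geometry = "random", seed = 42,
                     name = "toyA", net_charge = 1, mass_kda = 3.9)
b <- gen_toy_protein(8, c("ALA","VAL","PHE","THR","GLN","HIS","TRP","PRO"),
                     runif(8, 0.05, 0.95), geometry = "random", seed = 43,
                     name = "toyB", net_charge = -2, mass_kda = 3.6)

da <- sample_energy_distribution(a, neighbors(a), tab,
                                 selection_config(reps = 500000, seed = 1))
db <- sample_energy_distribution(b, neighbors(b), tab,
                                 selection_config(reps = 500000, seed = 2))
cfg <- kinetics_config(bias_voltage = 1.0)
dwa <- dwell_time(da, a, cfg)
dwb <- dwell_time(db, b, cfg)
dwa
#> <dwell_estimate> toyA: tau0 = 3.800e-08 s, tau = 3.778e-06 s [2.701e-06, 5.283e-06]
#>   beta^-1 = 1.000 eV, dE = -4.5993 +/- 0.3354 eV
dwb
#> <dwell_estimate> toyB: tau0 = 3.800e-08 s, tau = 2.663e-07 s [2.535e-07, 2.797e-07]
#>   beta^-1 = 2.000 eV, dE = -3.8940 +/- 0.0981 eV
compare_dwell(dwa, dwb)
#> # A tibble: 1 × 2
#>   log10_ratio separable
#>         <dbl> <lgl>
#> 1        1.15 TRUE
```

Reading the output: both toys share the same noninteracting transit
(`tau0` = 38 ns — 38 Å at the 0.1 m/s drift scale), but their interaction
energies and charge-set transition scales differ, so the central dwell
times end up more than an order of magnitude apart (`log10_ratio` 1.15)
with disjoint ±1σ ranges (`separable TRUE`): these two would be
distinguishable by dwell time alone.

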