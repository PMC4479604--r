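---
title: "Model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cleftsim simulates the first ten milliseconds after a single synaptic
vesicle releases its glutamate into an idealized cortical synapse, at the
level of individual molecules. This vignette documents the model, the
numerical methods, and the design decisions and limitations a user should
know before interpreting results.

## Geometry

A synapse is a pair of axis-aligned boxes (the pre- and postsynaptic
elements) facing each other across a 20 nm cleft, enclosed in a larger
"perisynaptic" box whose walls stand for the surrounding neuropil:

* The **postsynaptic density (PSD)** and the **active zone (AZ)** are
  congruent squares of side `Ls`, apposed across the cleft. The release
  point is the center of the AZ and the origin of coordinates.
* The elements are square prisms of side `La` (the total apposition,
  `Ls ≤ La ≤ 2 Ls`) and depth `element_height` (default `La`).
* The lateral gap `peri_gap` between the element walls and the
  perisynaptic walls is solved in closed form so that the extracellular
  space (ECS: everything inside the perisynaptic box that is not inside an
  element) occupies a target fraction (default 20%) of the world volume,
  and is clipped to the admissible 38–65 nm interval.

The 20% ECS balance is only attainable within those gap bounds when the
elements are large enough to dominate the world volume (roughly
`La ≳ 690` nm at the default element height). Smaller synapses — the
majority of a sampled cortical population — clip at the 38 nm bound, reach
an ECS fraction of 0.26–0.45, and `build_geometry()` warns. This is a
structural property of the box idealization, not a numerical failure; the
warning is informational and the headline statistics are computed over the
population as sampled.

The world is **closed**: glutamate cannot escape except by transporter
uptake. See "Limitations" below for the consequences.

```{r}
library(cleftsim)
g <- build_geometry(list(Ls = 400, La = 720))
geometry_volumes(g)
```

## Population sampling

`sample_configs()` draws synapse configurations from measured cortical
distributions:

* `Ls ~ logN(μ = 5.356, σ = 0.446)` on 60–825 nm. The location parameter
  derives from the log-normal fit of the PSD Feret diameter
  (`μ_DF = 5.828`) and the proportionality `Ls = 0.624 · D_F`:
  `μ_Ls = μ_DF + log 0.624 = 5.356` (`derive_ls_lognormal()`).
* `La` uniform on `[Ls, 2 Ls]`; AMPA receptor density uniform on
  500–3000 /µm²; transporter density uniform on 7000–12000 /µm².
* `nAMPA = round(density · Ls² · 1e-6)`, floored at one receptor.

Each configuration gets a deterministic sub-seed; sampling restores R's
global RNG state afterwards.

## Diffusion and reflection

Free glutamate performs Brownian motion with `D = 0.33 µm²/ms` and
`dt = 1 µs`: each coordinate receives a Gaussian step of standard deviation
`σ = sqrt(2 D dt) ≈ 25.7 nm`. Segments that cross a membrane are reflected
specularly, resolving up to 64 bounces per step; the rare step that
exceeds the bounce limit is discarded (the molecule stays put) and counted.
Oracles in the test suite verify the mean squared displacement against
`6 D t` to 1% and the uniformity of a non-reacting tracer's equilibrium
occupancy over the ECS.

## Surface binding

Receptors and transporters live on tiled rectangles (PSD tiles for
receptors; the apposed membrane rings outside the PSD/AZ, the element side
walls and the perisynaptic walls for transporters — one molecule per tile,
tile area the reciprocal of surface density). When a diffusion segment
crosses an occupied tile, binding occurs with probability

```
p = kon' · sqrt(π · dt / D) / A_tile
```

where `kon'` is the per-molecule association constant converted to
nm³/µs. The formula follows from equating the one-way crossing flux
through a tile per step, `c · σ / sqrt(2π) · A_tile`, to the mass-action
rate `kon · c · dt`. Membranes here are one-sided walls — molecules only
ever approach from the ECS — so the factor-of-two reduction appropriate
for surfaces sampled from both sides does not apply. The calibration is
validated against a bimolecular-depletion ODE in a well-mixed box.

## Gating kinetics

Kinetic schemes are YAML files (`inst/extdata/schemes/`), validated on
load: states, initial state, optional open state, transitions with order 1
(1/s) or 2 (1/(M·s)), and explicit ligand bookkeeping
(`releases_ligand`/`removes_ligand`), checked for consistency by a
breadth-first ligand count over the transition graph.

* **AMPA receptor**: a 7-state scheme (6 closed, 1 doubly liganded open)
  with three bimolecular binding steps, in the style of published
  room-temperature cortical AMPA receptor models. The scheme file is
  marked `TRANSCRIPTION-TO-VERIFY`: users holding the original rate table
  can drop in their own YAML without code changes.
* **Transporter**: a two-state uptake cycle — bimolecular capture
  (1.8×10⁷ /(M·s)), then equal-rate branches back to the ECS (release) or
  across the membrane (removal).

All rates are scaled by `Q10^((T − T_ref)/10)` with `Q10 = 2.5` from the
room-temperature reference to the 35 °C simulation temperature.

Unimolecular transitions use geometric next-event scheduling with
epoch-stamped events, exactly equivalent to an at-most-one-transition-per-
step discretization with `P(stay) = exp(−k_tot dt)`; at `dt = 1 µs` the
fastest unimolecular rates give `k dt < 0.01`. The test suite checks
stochastic ensembles against the exact master equation (matrix
exponential) and against the exact law of the discretized chain.

## Reproducibility

Every run draws from a counter-based RNG stream keyed by
`(root seed, configuration id, run index)` (splitmix64-seeded
xoshiro256++), so run `k` of configuration `i` is bit-reproducible in
isolation, independent of execution order and of R's global RNG. Molecule
placement is keyed by the configuration's sub-seed.

## Outputs and analysis

Each run records the open-receptor count per microsecond and reduces it to
`maxOPEN` (peak open count), `peak_time` (first time the peak is attained,
µs) and `auc`. `simulate_population()` aggregates per-configuration
means/CVs and keeps the pooled per-run table; `headline_statistics()`
computes the population summaries (structural correlations, pooled
mean/median maxOPEN, peak-time mean, fraction of runs ≤ 100).
`fit_power_law()` fits `y = a x^b + c` by Levenberg–Marquardt with
held-out validation via `validate_fit()`; `maxopen_distribution()`,
`activation_probability()` and `spatial_opening_map()` cover the
distributional and spatial analyses. The `exec/cleftsim` script chains
`sample → simulate → analyze` resumably on disk.

## Problem sizes

With the default 3000 molecules and 10 000 steps, one run of a median
synapse takes on the order of 0.1 s on one core; the desk-scale population
(30 configurations × 50–60 runs) takes a few minutes, and the full-study
scale (500 × 500) several hours.

## Limitations

* **Closed world.** The perisynaptic box seals the synapse; glutamate
  leaves only by transporter uptake. A sub-millimolar glutamate tail
  therefore persists for hundreds of microseconds, which sustains late
  receptor openings and biases the *peak-time* distribution upward
  relative to an open geometry where glutamate escapes into the neuropil.
  Peak *amplitude* statistics (maxOPEN and its correlates) are dominated
  by the first ~100 µs and are robust to this choice.
* **Rate-table transcription.** The AMPA scheme is a transcription of a
  published room-temperature model; statistics that depend on the detailed
  balance of desensitization vs. opening (notably peak times) are
  sensitive to the exact table, while structural correlations are not.
* **Box idealization.** Real synapses are not rectangular; curvature,
  astrocytic coverage and extrasynaptic receptor pools are outside the
  model.
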