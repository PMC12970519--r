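---
title: "Models and methods behind dybe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dybe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dybe)
```

This vignette documents the models the package implements, the parameters
that matter, the design decisions taken where the method left room, and
what the synthetic benchmarks do and do not demonstrate about real data.

## The dual-kinetic model

A target site is described by two nested two-state continuous-time Markov
processes:

* **Binder layer.** The site alternates between *unbound* and *bound* with
  exponential dwell times at pseudo-first-order rates
  $k_\mathrm{on,b} c_\mathrm{b}$ (per s, association) and
  $k_\mathrm{off,b}$ (dissociation). Solution concentrations are treated
  as constant: no depletion, no rebinding memory. The stationary occupancy
  is $f_\mathrm{occ} = k_\mathrm{on,b}c_\mathrm{b} /
  (k_\mathrm{on,b}c_\mathrm{b} + k_\mathrm{off,b})$.
* **Imager layer.** While the binder is present, its docking strand
  alternates *dark*/*bright* at rates $k_\mathrm{on,i} c_\mathrm{i}$ and
  $k_\mathrm{off,i}$. A bright interval is truncated the moment the binder
  unbinds, because the docking strand (and any hybridized imager) leaves
  with it.

`simulate_site_trace()` realizes this scheme with an exact event-driven
simulation (implemented in C++): no time discretization is involved in the
kinetics; camera frames only quantize the *output* localizations. Under
dynamic exchange the initial binder state is drawn from the stationary
occupancy, which models binders equilibrating with the sample before the
acquisition starts.

**Classical mode** models label-then-wash experiments: the initial
occupancy is a Bernoulli draw from
$f_\mathrm{occ}(1 - e^{-(k_\mathrm{on,b}c_\mathrm{b} +
k_\mathrm{off,b})t_\mathrm{label}})$ and the rebinding rate is zero
afterwards, so occupancy decays as $e^{-k_\mathrm{off,b}t}$ during
acquisition.

**Detection criterion.** A site is detected when at least one bright
interval of duration at least `min_on_time` (default: one camera frame)
falls inside the acquisition window. There is no photon-budget model — the
method description gives no photon statistics — so `min_on_time` is the
single knob standing in for "bright long enough to be localized".

**Mode coupling.** `detection_probability()` and `scan_detection()`
evaluate both modes from *one* trajectory per site: classical detection is
restricted to the initial binder dwell (where the two processes are
statistically identical) and gated by the labeling-equilibration
probability. This is a genuine coupling, so the cell-wise dominance of
dynamic exchange over classical labeling holds by construction rather
than only in expectation, which is exactly the claim the condition scan is
meant to establish.

### Default kinetic parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `k_on_binder` | 1e-3 | /nM/s | typical nanobody association (1e6 /M/s) |
| `c_binder` | 20 | nM | optimized working concentration for exchange imaging |
| `k_off_binder` | 0.08 | /s | a high-off-rate nanobody (dwell ~12 s), occupancy 0.2 |
| `k_on_imager` | 6e-3 | /nM/s | standard DNA-PAINT docking/imager pair |
| `c_imager` | 1 | nM | classical baseline; scans use 1–2 x |
| `k_off_imager` | 2 | /s | 0.5 s mean bright time |

Acquisition defaults: 0.1 s frames, 10 000 frames (T = 1000 s), 5 nm
localization precision, 130 nm pixels, 20 x 20 µm field. The linkage
offset defaults to 0 — probe geometry is a motivation for small binders,
not a fitted quantity — and is exposed (`linkage_offset`) to study whether
offset resampling across binder events can fake dimers (see the monomer
control below).

## Synthetic data generator

`generate_ground_truth()` draws a Poisson number of protein complexes at
the configured density, positions them uniformly, and assigns species
(`mono_A`, `mono_B`, `homo_AA`, `homo_BB`, `hetero_AB`, or the symmetric
shorthand `mono`/`homo`/`hetero`). Dimer partners sit at exactly
`dimer_distance` (default 15 nm, the receptor-dimer scale) in a uniform
random direction. Geometry is strictly 2D — membrane receptors imaged in
TIRF — and **periodic**: all synthetic coordinates live on a torus and the
NND routines offer the matching minimum-image metric. The torus removes
edge bias, so recovery benchmarks measure estimator error, not boundary
handling; for experimental (non-periodic) data the Euclidean metric with a
border-exclusion margin is provided instead.

`simulate_localizations()` renders one localization per frame that a
bright interval covers for at least `min_on_time`, at the protein position
plus the linkage offset (direction resampled per binder binding event)
plus isotropic Gaussian error `sigma_loc`. Because offset directions are
uniform, localization centroids are unbiased for the protein position.
`add_nonspecific()` appends CSR background events (one localization each —
no background blinking model). Note a numerical detail: frame coverage is
tested with a tolerance of 1e-9 frame times because floating-point
cancellation at frame boundaries (e.g. `1.3 - 1.2 < 0.1`) would otherwise
drop fully covered frames.

What the generator deliberately does **not** emulate: camera noise and PSF
shape, dye photophysics (bleaching, intrinsic blinking), drift, z, and
chromatic registration error. Passing recovery tests on this generator
therefore shows that the *inference* is correct under the stated model,
not that the model captures every failure mode of real microscopes.

## Nearest-neighbor statistics

`kth_nnd()`/`cross_nnd()` identify neighbors with a kd-tree (RANN; torus
handled by 3 x 3 tiling) and then recompute distances from the coordinates
with the per-axis minimum-image formula. This split matters: the test
suite contains a brute-force all-pairs oracle using the same formula, so
whenever both routes pick the same neighbor the distances agree *exactly*
(bitwise), and ties between distinct neighbors occur with probability zero
for continuous data. The CSR reference is analytic,
$F_k(r) = 1 - \sum_{j<k} e^{-\rho\pi r^2}(\rho\pi r^2)^j/j!$, with the
intensity $\rho$ estimated from the same point set and field area —
matching the "CSR at observed density" convention used when overlaying
such curves on receptor data. Histograms default to 5 nm bins over
0–200 nm; the source material does not state its binning, and this covers
the receptor scale.

## Labeling-efficiency estimation

The reference-tag workflow compares the cross-NND histogram from reference
positions to target positions against a simulation-defined model family
indexed by the labeling efficiency (LE): references are CSR at the
observed density; each is detected with probability LE at a fixed-length
offset (default 0; the reference tag is intracellular and the binder
extracellular, so a real offset exists but is unstated — it is a config
knob) plus Gaussian noise `measurement_sd` (default: quadrature sum of the
two channels' cluster-centroid precisions, else 10 nm). Undetected
references fall back to the CSR background of detected targets, which is
what anchors the estimate at low LE.

Design choices:

* **Grid fit, not gradient optimization.** The model is simulation-defined
  and noisy; the objective is the sum of squared differences of normalized
  densities over 0–200 nm. The grid runs a coarse pass at five times
  `grid_step` (default 0.01) and refines around the coarse minimum, so the
  reported grid satisfies the same contract (strictly increasing, estimate
  attained on it) at a fifth of the simulations.
* **Common random numbers.** All grid points share one seed, and detection
  is implemented as one uniform draw per reference compared against LE, so
  detected sets are nested along the grid and the objective is smooth in
  LE. This is what makes ±0.05 recovery possible with few replicates
  (default 3).
* Estimates are invariant to global translation of both channels (the
  statistic only uses relative distances); this is tested.

Note what this estimates on real pipelines: the *effective* efficiency —
chemical labeling times blink detection times clustering yield — which is
precisely the quantity the reference-tag experiment measures per cell.

`cluster_localizations()` supplies the protein positions: single-linkage
components of the within-`link_radius` graph, keeping components with at
least `min_locs` members (which removes single-blink background), located
at their precision-weighted centroid.

## Stoichiometry decomposition

`fit_species_fractions()` fits fractions of candidate species by matching
the three first-NND histograms (A→A, B→B, A→B) of simulated mixtures to
the data, with per-channel labeling efficiencies supplied as *inputs*
(measured upstream by the reference-tag fit, mirroring the two-step usage)
rather than co-fitted. For each candidate fraction vector the total
complex count is chosen so that the efficiency-corrected molecule count
matches the observation ($n_A/\mathrm{LE}_A + n_B/\mathrm{LE}_B$); a
candidate whose channel ratio disagrees with the data is thereby penalized
through the simulated densities. The simplex is searched on a coarse grid
(step 0.05) with local refinement (step 0.01), under common random numbers
across candidates. Only first NNDs enter the objective — that is the
evidence receptor-dimer analyses display — while k-th-order hooks remain
available in `kth_nnd()`.

The symmetric candidate set `c("mono", "homo", "hetero")` (equal A/B
split) is the default and keeps the simplex two-dimensional; the five
channelled species are supported but enlarge the search combinatorially.

`apparent_dimer_fraction()` is the hallucination control: the fraction of
points with first NND below a dimer-scale window minus the CSR expectation
at observed density, floored at zero. The end-to-end monomer control (high
off-rate binder, 6 nm linkage offset, clustering on) keeps this at the CSR
level because blinks from successive binder events land within the linkage
diameter and are merged into one cluster.

## Condition scans

`scan_detection()` maps the coupled detection probabilities over a default
grid of seven log-spaced off-rates (1e-4–1 /s), binder concentrations
{1, 5, 10, 20, 50} nM bracketing the 20 nM working point, and imager
concentrations at {1, 1.5, 2} x the classical baseline — the 1.5-fold
excess being the working choice that equalizes imager binding frequencies
between the modes. 2000 sites per cell keep the full 105-cell scan around
a second of CPU thanks to the event-driven core and early exit once a
site's outcome is settled. `recommend_conditions()` filters cells reaching
a threshold (default 0.9, "robust detection" — the criterion value is not
externally specified and is configurable) and sorts them cheapest-first.

## Randomness and determinism

Every stochastic function takes a `seed` and restores the caller's RNG
state (`withr::with_seed`); the C++ core draws from R's RNG, so a seed
fixes the full trajectory set. Within one call, sites are simulated
sequentially from a single stream — results are deterministic given the
seed, though not invariant to reordering sites. `run_pipeline()` writes
CSV/JSON artifacts and hashes file bytes into a manifest; identical
configurations reproduce identical manifests (HDF5 export exists alongside
but embeds object metadata, so the pipeline's determinism contract is on
the CSV path).

## Problem sizes used in the validation suite

The bundled tests and `scripts/acceptance.R` run at sizes chosen to give
tight Monte Carlo error at desk scale: 1e5 s trajectories for the
occupancy oracle (time-average SE below 2% for all sampled rates), 1e4
sites for the classical-limit check, 2000 sites per scan cell, 1e4 points
for the CSR closed form, 5000 reference proteins and 20 seeded runs per
truth level for labeling-efficiency recovery, about 5000 ground-truth
molecules per channel for the stoichiometry recovery, and 4000 monomers
for the hallucination control.

## Known limitations

* **Close homodimers merge under clustering.** Single-linkage clustering
  with `link_radius` larger than the dimer distance fuses same-channel
  dimer partners into one cluster; stoichiometry on clustered positions is
  then biased toward monomers. Use `link_radius` below the expected dimer
  distance (blink clouds permitting), or fit on positions obtained
  independently. Heterodimers are immune (partners live in different
  channels).
* The labeling-efficiency model family assumes CSR references; strongly
  clustered targets violate it and the estimate inherits bias.
* No photophysics, camera noise, drift, or 3D; densities are homogeneous.
* The stoichiometry search covers monomers and dimers; higher-order
  oligomers are out of scope.
* Occupancy formulas assume constant solution concentration; strong local
  depletion (very dense targets, low binder concentration) is not modeled.
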