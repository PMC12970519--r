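# dybe

Simulation and inference tools for DNA-PAINT super-resolution experiments
that keep DNA-conjugated binders (typically nanobodies) in solution during
acquisition — *dynamic binder exchange* (DyBE) — instead of labeling once
and washing.

## The problem

DNA-PAINT localizes proteins through transient hybridization of
dye-labeled *imager* strands to a *docking* strand carried by an affinity
binder. With classical labeling, a protein is only detectable if a binder
is still sitting on it during acquisition, so for small binders with high
off-rates the detectable fraction collapses to the equilibrium occupancy

    f_occ = k_on,binder · c_binder / (k_on,binder · c_binder + k_off,binder)

times the post-wash survival `exp(-k_off,binder · t)`. Dynamic binder
exchange leaves binders in solution so that every target site is sampled
repeatedly: the blinking a site produces is the convolution of two coupled
kinetic layers, (i) binder–target exchange (rates `k_on,binder · c_binder`
and `k_off,binder`) and (ii) imager–docking hybridization (rates
`k_on,imager · c_imager` and `k_off,imager`). Weak binders lose dwell time
but gain replenishment, so detection probability stays high where
classical labeling fails.

The package provides, for users of localization microscopy who want to
plan or analyze such experiments:

* **kinetics** — closed-form occupancy and event rates plus an exact
  event-driven (Gillespie-style) simulator of the nested two-state process,
  including blink truncation when the binder departs
  (`steady_state_occupancy()`, `classical_occupancy()`,
  `simulate_site_trace()`, `detection_probability()`);
* **synthetic data** — ground-truth fields of monomers / homodimers /
  heterodimers in two channels, Bernoulli labeling, blink-accurate
  localization rendering with linkage offsets and localization error, CSR
  background, and Picasso-dialect HDF5 / CSV I/O
  (`generate_ground_truth()`, `simulate_localizations()`, `write_locs()`);
* **NND statistics** — k-th and cross nearest-neighbor distances (kd-tree
  accelerated, torus or border-corrected Euclidean metrics) and the CSR
  reference CDF `1 − exp(−ρπr²)` and its k-th-order Poisson-tail extension
  (`kth_nnd()`, `cross_nnd()`, `csr_nnd_cdf()`, `nnd_histogram()`);
* **labeling efficiency** — the reference-tag workflow: cluster blinks into
  protein positions and fit the reference→target cross-NND histogram
  against a simulated model family indexed by labeling efficiency
  (`cluster_localizations()`, `estimate_labeling_efficiency()`);
* **stoichiometry** — SPINNA-style decomposition of the three first-NND
  histograms (A→A, B→B, A→B) into monomer / homodimer / heterodimer
  fractions given per-channel labeling efficiencies
  (`fit_species_fractions()`, `apparent_dimer_fraction()`);
* **condition scans** — detection-probability maps over binder off-rate
  and probe concentrations for both modes, with threshold-based
  recommendations (`scan_detection()`, `recommend_conditions()`).

Everything takes and returns tibbles, fitted objects support `tidy()` /
`glance()` / `autoplot()`, and `run_pipeline()` drives the whole chain
from a YAML config with a hashed artifact manifest.

## Worked example

How much detection does dynamic exchange buy for a weak binder
(`k_off = 0.08 /s`, 20 nM, occupancy 0.2) over a 1000 s acquisition?

```r
library(dybe)

model <- kinetic_model(k_on_binder = 1e-3, c_binder = 20, k_off_binder = 0.08)
steady_state_occupancy(model)
#> [1] 0.2

acq <- acquisition_settings(n_frames = 10000)   # 0.1 s frames, T = 1000 s
detection_probability(model, acq, mode = "both", t_label = 3600,
                      n_sites = 5000, seed = 1)
#> # A tibble: 2 × 6
#>   mode      n_sites n_detected detection_probability   ci_lo  ci_hi
#>   <chr>       <int>      <int>                 <dbl>   <dbl>  <dbl>
#> 1 dybe         5000       3059                0.612  0.598   0.625
#> 2 classical    5000         52                0.0104 0.00778 0.0136
```

The same trajectories, split into the two modes: classical labeling
detects 1% of sites, dynamic exchange 61%.

Estimating labeling efficiency with the reference-tag workflow — every
target protein carries a stable reference signal (channel A); the tested
binder detects it in channel B with unknown efficiency:

```r
field <- list(width = 20000, height = 20000)           # nm
gt  <- generate_ground_truth(
  species_mix(c(hetero_AB = 1), dimer_distance = 1, density = 12.5),
  field, seed = 11)
lab <- apply_labeling(gt, c(A = 1, B = 0.6), seed = 12)   # true efficiency 0.6

# 7 nm centroid noise per channel -> 10 nm pair noise in quadrature
set.seed(13)
pos <- as.data.frame(lab)
pos$x <- (pos$x + rnorm(nrow(pos), 0, 7)) %% field$width
pos$y <- (pos$y + rnorm(nrow(pos), 0, 7)) %% field$height

fit <- estimate_labeling_efficiency(pos[pos$channel == "A", ],
                                    pos[pos$channel == "B", ],
                                    field, seed = 14, measurement_sd = 10)
fit
#> <le_fit> labeling efficiency estimate 0.59 (objective 5.491e-06)
#>   4958 reference / 2949 target positions, model sd 10 nm, 30 grid points
```

The grid fit recovers the simulated 0.60 as 0.59. `autoplot(fit)` shows
the objective over the efficiency grid; `tidy(fit)` returns it.

Which conditions give robust detection across binder off-rates?

```r
scan <- scan_detection(kinetic_model(), acq = acquisition_settings(),
                       n_sites = 2000, seed = 15)
recommend_conditions(scan, threshold = 0.9)
#> # A tibble: 51 × 9
#>   k_off_binder c_binder c_imager mode  n_sites n_detected detection ci_lo ci_hi
#>          <dbl>    <dbl>    <dbl> <chr>   <int>      <int>     <dbl> <dbl> <dbl>
#> 1       0.0001        1      1   dybe     2000       1881     0.940 0.929 0.950
#> 2       0.0001        1      1.5 dybe     2000       1917     0.958 0.949 0.967
#> 3       0.0001        1      2   dybe     2000       1924     0.962 0.953 0.970
#> 4       0.0001        5      1   dybe     2000       1980     0.99  0.985 0.994
#> # ℹ 47 more rows
```

51 of the 105 grid cells reach 90% detection under dynamic exchange,
sorted cheapest-first in binder and imager concentration.

See `vignette source in vignettes/dybe-methods.Rmd` for the model
assumptions, parameter choices, and known limitations.

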