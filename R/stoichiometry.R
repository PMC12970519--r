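# NND-based stoichiometry decomposition: fit the fractions of monomer /
# homodimer / heterodimer species by matching the three first-NND
# histograms (A->A, B->B, A->B) of simulated mixtures to the data, given
# per-channel labeling efficiencies measured upstream.

mixture_pair_names <- c("AA", "BB", "AB")

# three normalized first-NND histograms from two channel point sets
mixture_histograms <- function(xy_A, xy_B, field, bin_edges) {
  widths <- diff(bin_edges)
  nb <- length(widths)
  one <- function(d) {
    if (length(d) == 0) return(rep(0, nb))
    idx <- findInterval(d, bin_edges)
    tabulate(idx[idx >= 1 & idx <= nb], nbins = nb) / (length(d) * widths)
  }
  dAA <- if (nrow(xy_A) >= 2) kth_nnd(xy_A, 1, "torus", field) else numeric(0)
  dBB <- if (nrow(xy_B) >= 2) kth_nnd(xy_B, 1, "torus", field) else numeric(0)
  dAB <- if (nrow(xy_A) >= 1 && nrow(xy_B) >= 1) {
    cross_nnd(xy_A, xy_B, "torus", field)
  } else numeric(0)
  rbind(AA = one(dAA), BB = one(dBB), AB = one(dAB))
}

#' Simulate the three first-NND histograms of a species mixture
#'
#' Generates a ground-truth field from the mixture
#' ([generate_ground_truth()]), thins each channel by its labeling
#' efficiency ([apply_labeling()]), adds isotropic Gaussian position noise,
#' and returns the normalized first-NND histograms of the A->A, B->B and
#' A->B channel pairs, averaged over replicates.
#'
#' @param mix a [species_mix()].
#' @param le_A,le_B per-channel labeling efficiencies in (0, 1\].
#' @param measurement_sd per-axis Gaussian position noise (nm).
#' @param field field geometry (nm).
#' @param n_replicates simulated fields to average.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @param bin_edges histogram bin edges (nm).
#' @return A tibble with columns `pair` (`"AA"`, `"BB"`, `"AB"`),
#'   `bin_lo`, `bin_hi`, `density`.
#' @export
simulate_mixture_nnd <- function(mix, le_A = 1, le_B = 1, measurement_sd = 10,
                                 field, n_replicates = 1, seed = NULL,
                                 bin_edges = seq(0, 200, by = 5)) {
  stopifnot(inherits(mix, "species_mix"))
  check_fraction(le_A, "le_A"); check_fraction(le_B, "le_B")
  f <- as_field(field)
  widths <- diff(bin_edges)
  nb <- length(widths)
  with_seed(seed, {
    acc <- matrix(0, nrow = 3, ncol = nb,
                  dimnames = list(mixture_pair_names, NULL))
    for (i in seq_len(n_replicates)) {
      gt <- generate_ground_truth(mix, f)
      lab <- apply_labeling(gt, c(A = le_A, B = le_B))
      if (nrow(lab) > 0) {
        x <- wrap_coord(lab$x + rnorm(nrow(lab), 0, measurement_sd), f$width)
        y <- wrap_coord(lab$y + rnorm(nrow(lab), 0, measurement_sd), f$height)
        xy_A <- cbind(x[lab$channel == "A"], y[lab$channel == "A"])
        xy_B <- cbind(x[lab$channel == "B"], y[lab$channel == "B"])
        acc <- acc + mixture_histograms(xy_A, xy_B, f, bin_edges)
      }
    }
    acc <- acc / n_replicates
    tibble(pair = rep(mixture_pair_names, each = nb),
           bin_lo = rep(bin_edges[-length(bin_edges)], times = 3),
           bin_hi = rep(bin_edges[-1], times = 3),
           density = as.vector(t(acc)))
  })
}

# all nonnegative integer vectors of length k summing to s (simplex grid)
integer_compositions <- function(k, s) {
  if (k == 1) return(matrix(s, ncol = 1))
  out <- list()
  for (i in 0:s) {
    rest <- integer_compositions(k - 1, s - i)
    out[[length(out) + 1]] <- cbind(i, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

#' Fit species fractions from two-channel protein positions
#'
#' Decomposes a two-channel point pattern into monomer / homodimer /
#' heterodimer fractions: for every candidate fraction vector on a simplex
#' grid, a mixture field matching the implied molecule counts (observed
#' counts corrected by the labeling efficiencies) is simulated with
#' [simulate_mixture_nnd()] under common random numbers, and the summed
#' squared difference of the three first-NND histograms (A->A, B->B, A->B)
#' is minimized.  A coarse pass at `grid_step` is refined locally at
#' `refine_step`.
#'
#' @param positions_A,positions_B protein positions per channel (tables
#'   with `x`, `y` in nm).
#' @param candidate_species species whose fractions are fitted: a subset of
#'   `c("mono_A","mono_B","homo_AA","homo_BB","hetero_AB")`, or the
#'   symmetric shorthand `c("mono","homo","hetero")` (equal A/B split).
#' @param le_A,le_B per-channel labeling efficiencies in (0, 1\] (inputs
#'   from [estimate_labeling_efficiency()], not co-fitted).
#' @param field field geometry (nm).
#' @param grid_step coarse simplex resolution.
#' @param refine_step local refinement resolution.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @param dimer_distance intra-dimer distance assumed in the model (nm).
#' @param measurement_sd per-axis position noise assumed in the model (nm).
#' @param bin_edges histogram bin edges (nm).
#' @param n_replicates simulated fields averaged per candidate.
#' @return An object of class `stoich_fit`: list with `species_fractions`
#'   (named, sums to 1), `objective`, `grid` (all evaluated candidates),
#'   `grid_resolution`, `labeling_efficiencies`, `n_A`, `n_B`.  `tidy()`
#'   returns the fractions, `glance()` the one-row summary.
#' @export
fit_species_fractions <- function(positions_A, positions_B,
                                  candidate_species = c("mono", "homo", "hetero"),
                                  le_A, le_B, field,
                                  grid_step = 0.05, refine_step = 0.01,
                                  seed = NULL, dimer_distance = 15,
                                  measurement_sd = 10,
                                  bin_edges = seq(0, 200, by = 5),
                                  n_replicates = 2) {
  xy_A <- as_xy(positions_A, "positions_A")
  xy_B <- as_xy(positions_B, "positions_B")
  if (nrow(xy_A) == 0 || nrow(xy_B) == 0) {
    abort("both channels must be non-empty.", class = "dybe_argument_error")
  }
  if (length(candidate_species) == 0) {
    abort("`candidate_species` must be non-empty.",
          class = "dybe_argument_error")
  }
  if (!(le_A > 0 && le_A <= 1 && le_B > 0 && le_B <= 1)) {
    abort("labeling efficiencies must be in (0, 1].",
          class = "dybe_argument_error")
  }
  f <- as_field(field)
  area <- field_area_um2(f)
  k <- length(candidate_species)
  data_h <- mixture_histograms(xy_A, xy_B, f, bin_edges)
  # implied total molecule count, efficiency-corrected
  n_mol <- nrow(xy_A) / le_A + nrow(xy_B) / le_B
  # molecules per complex contributed by one unit of each candidate
  mol_per <- purrr::map_dbl(candidate_species, function(sp) {
    fr <- expand_species_fractions(setNames(1, sp))
    sum(purrr::map_dbl(names(fr), function(s) fr[[s]] * sum(.species_channels[[s]])))
  })
  seed_use <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else
    as.integer(seed)

  objective <- function(frac) {
    m <- sum(frac * mol_per)
    if (m <= 0) return(Inf)
    dens <- (n_mol / m) / area
    mix <- species_mix(setNames(frac, candidate_species),
                       dimer_distance = dimer_distance, density = dens)
    sim <- simulate_mixture_nnd(mix, le_A, le_B, measurement_sd, f,
                                n_replicates, seed = seed_use,
                                bin_edges = bin_edges)
    nb <- length(bin_edges) - 1
    sim_m <- matrix(sim$density, nrow = 3, byrow = TRUE,
                    dimnames = list(mixture_pair_names, NULL))
    sum((data_h - sim_m)^2)
  }

  s_coarse <- round(1 / grid_step)
  coarse <- integer_compositions(k, s_coarse) / s_coarse
  obj_coarse <- apply(coarse, 1, objective)
  best_c <- coarse[which.min(obj_coarse), ]

  # local refinement on the refine_step lattice within +/- grid_step
  ratio <- round(grid_step / refine_step)
  if (ratio > 1) {
    base <- round(best_c / refine_step)
    span <- -ratio:ratio
    deltas <- as.matrix(expand.grid(rep(list(span), k - 1)))
    deltas <- cbind(deltas, -rowSums(deltas))
    cand <- sweep(deltas, 2, base, "+")
    ok <- rowSums(cand < 0) == 0 & abs(rowSums(cand) - round(1 / refine_step)) < 1e-9 &
      apply(abs(deltas) <= ratio, 1, all)
    cand <- unique(cand[ok, , drop = FALSE]) * refine_step
    obj_fine <- apply(cand, 1, objective)
    all_frac <- rbind(coarse, cand)
    all_obj <- c(obj_coarse, obj_fine)
  } else {
    all_frac <- coarse
    all_obj <- obj_coarse
  }
  best <- which.min(all_obj)
  fractions <- setNames(all_frac[best, ], candidate_species)
  dimnames(all_frac) <- list(NULL, candidate_species)
  grid <- as_tibble(as.data.frame(all_frac))
  grid$objective <- all_obj
  structure(list(
    species_fractions = fractions,
    objective = all_obj[best],
    grid = grid,
    grid_resolution = refine_step,
    labeling_efficiencies = c(A = le_A, B = le_B),
    dimer_distance = dimer_distance,
    measurement_sd = measurement_sd,
    n_A = nrow(xy_A), n_B = nrow(xy_B)
  ), class = "stoich_fit")
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat("<stoich_fit>\n  fractions:",
      paste(sprintf("%s=%.3g", names(x$species_fractions),
                    x$species_fractions), collapse = ", "), "\n")
  cat(sprintf("  objective %.4g at resolution %.3g; LE A=%.3g B=%.3g; n_A=%d n_B=%d\n",
              x$objective, x$grid_resolution, x$labeling_efficiencies["A"],
              x$labeling_efficiencies["B"], x$n_A, x$n_B))
  invisible(x)
}

#' Apparent excess dimer fraction of a point pattern
#'
#' Fraction of points whose first NND falls below a dimer-scale window,
#' minus the fraction expected under complete spatial randomness at the
#' observed density, floored at zero.  Used as the hallucination control:
#' transient binder exchange with a nonzero linkage offset must not create
#' spurious short-distance pairs from monomeric targets.
#'
#' @param positions a table with `x`, `y` (nm).
#' @param dimer_distance_window window below which a neighbor counts as a
#'   putative dimer partner (nm).
#' @param field field geometry (nm).
#' @param metric `"torus"` or `"euclidean"`.
#' @return Excess fraction in \[0, 1\].
#' @export
apparent_dimer_fraction <- function(positions, dimer_distance_window = 20,
                                    field, metric = c("torus", "euclidean")) {
  metric <- match.arg(metric)
  xy <- as_xy(positions, "positions")
  if (nrow(xy) < 2) {
    abort("need at least 2 points.", class = "dybe_argument_error")
  }
  f <- as_field(field)
  d <- kth_nnd(xy, 1, metric, f,
               border_margin = if (metric == "euclidean")
                 dimer_distance_window else 0)
  rho <- nrow(xy) / (f$width * f$height)  # per nm^2
  p_obs <- mean(d < dimer_distance_window)
  p_csr <- csr_nnd_cdf(rho, dimer_distance_window, k = 1)
  max(0, p_obs - p_csr)
}
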