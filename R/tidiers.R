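# broom-style accessors for fitted objects

#' Tidy a labeling-efficiency fit
#'
#' @param x an `le_fit` from [estimate_labeling_efficiency()].
#' @param ... unused.
#' @return The efficiency grid with per-point objectives.
#' @export
tidy.le_fit <- function(x, ...) {
  x$grid
}

#' @rdname tidy.le_fit
#' @return For `glance()`: a one-row summary (`estimate`, `objective_min`,
#'   `n_ref`, `n_tgt`, `measurement_sd`).
#' @export
glance.le_fit <- function(x, ...) {
  tibble(estimate = x$estimate, objective_min = x$objective_min,
         n_ref = x$n_ref, n_tgt = x$n_tgt,
         measurement_sd = x$measurement_sd)
}

#' Tidy a stoichiometry fit
#'
#' @param x a `stoich_fit` from [fit_species_fractions()].
#' @param ... unused.
#' @return One row per fitted species with its fraction.
#' @export
tidy.stoich_fit <- function(x, ...) {
  tibble(species = names(x$species_fractions),
         fraction = unname(x$species_fractions))
}

#' @rdname tidy.stoich_fit
#' @return For `glance()`: a one-row summary.
#' @export
glance.stoich_fit <- function(x, ...) {
  tibble(objective = x$objective, grid_resolution = x$grid_resolution,
         le_A = unname(x$labeling_efficiencies["A"]),
         le_B = unname(x$labeling_efficiencies["B"]),
         n_A = x$n_A, n_B = x$n_B)
}
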