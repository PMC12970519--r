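# Condition optimization: map detection probability over grids of binder
# off-rate and probe concentrations, for DyBE and classical modes, and
# recommend the cheapest conditions that reach a detection threshold.

#' Default condition-scan axes
#'
#' Binder off-rates log-spaced over 1e-4 to 1 per second (seven points),
#' binder concentrations bracketing the optimized 20 nM working point, and
#' imager concentrations at 1x / 1.5x / 2x a classical baseline.
#'
#' @param c_imager_baseline classical imager concentration (nM).
#' @return Named list of axes for [scan_detection()].
#' @export
default_scan_axes <- function(c_imager_baseline = 1) {
  list(k_off_binder = 10^seq(-4, 0, length.out = 7),
       c_binder = c(1, 5, 10, 20, 50),
       c_imager = c_imager_baseline * c(1, 1.5, 2))
}

#' Scan detection probability over kinetic conditions
#'
#' Evaluates [detection_probability()] for DyBE and classical modes on the
#' Cartesian grid of `k_off_binder`, `c_binder` and `c_imager`, holding the
#' remaining parameters of `base_model` fixed.  Each grid cell simulates
#' `n_sites` coupled trajectories, so the classical estimate never exceeds
#' the DyBE estimate within a cell.
#'
#' @param base_model a [kinetic_model()] supplying the fixed parameters.
#' @param axes named list with numeric vectors `k_off_binder` (per s),
#'   `c_binder` (nM), `c_imager` (nM); see [default_scan_axes()].
#' @param acq an [acquisition_settings()].
#' @param t_label classical-mode labeling incubation time (s).
#' @param n_sites simulated sites per grid cell.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return A tibble of class `scan_result` in long format: `k_off_binder`,
#'   `c_binder`, `c_imager`, `mode`, `n_sites`, `n_detected`, `detection`,
#'   `ci_lo`, `ci_hi`.
#' @export
scan_detection <- function(base_model, axes = default_scan_axes(base_model$c_imager),
                           acq = acquisition_settings(), t_label = 3600,
                           n_sites = 2000, seed = NULL) {
  stopifnot(inherits(base_model, "kinetic_model"),
            inherits(acq, "acquisition_settings"))
  need <- c("k_off_binder", "c_binder", "c_imager")
  if (!all(need %in% names(axes)) ||
      any(purrr::map_int(axes[need], length) == 0)) {
    abort("`axes` must provide non-empty k_off_binder, c_binder, c_imager.",
          class = "dybe_argument_error")
  }
  grid <- tidyr::expand_grid(k_off_binder = axes$k_off_binder,
                             c_binder = axes$c_binder,
                             c_imager = axes$c_imager)
  out <- with_seed(seed, {
    purrr::pmap_dfr(grid, function(k_off_binder, c_binder, c_imager) {
      m <- kinetic_model(base_model$k_on_binder, c_binder, k_off_binder,
                         base_model$k_on_imager, c_imager,
                         base_model$k_off_imager)
      det <- detection_probability(m, acq, mode = "both", t_label = t_label,
                                   n_sites = n_sites, seed = NULL)
      mutate(det, k_off_binder = k_off_binder, c_binder = c_binder,
             c_imager = c_imager, .before = 1)
    })
  })
  out <- dplyr::rename(out, detection = "detection_probability")
  attr(out, "axes") <- axes
  attr(out, "t_label") <- t_label
  attr(out, "acq") <- acq
  class(out) <- c("scan_result", class(out))
  out
}

#' Recommend conditions meeting a detection threshold
#'
#' Grid cells whose DyBE detection probability reaches the threshold,
#' sorted cheapest-first (ascending binder concentration, then imager
#' concentration).
#'
#' @param scan a [scan_detection()] result.
#' @param threshold required detection probability (default 0.9,
#'   "robust detection").
#' @return Tibble of recommended cells (possibly empty).
#' @export
recommend_conditions <- function(scan, threshold = 0.9) {
  stopifnot(inherits(scan, "scan_result"))
  as_tibble(scan) %>%
    filter(.data$mode == "dybe", .data$detection >= threshold) %>%
    arrange(.data$c_binder, .data$c_imager, .data$k_off_binder)
}
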