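#' Equilibrium binder occupancy of a target site
#'
#' Under dynamic binder exchange the binder continuously samples the target
#' with pseudo-first-order on-rate `k_on_binder * c_binder` and off-rate
#' `k_off_binder`; the stationary probability that a site carries a binder
#' is
#' \deqn{f_{occ} = \frac{k_{on}c}{k_{on}c + k_{off}}.}
#' Solution concentration is assumed constant (no depletion).
#'
#' @param model a [kinetic_model()].
#' @return Occupied fraction in \[0, 1\].
#' @examples
#' steady_state_occupancy(kinetic_model(1e-3, 20, 0.08))  # 0.2
#' @export
steady_state_occupancy <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  konc <- model$k_on_binder * model$c_binder
  koff <- model$k_off_binder
  if (konc + koff <= 0) {
    abort("occupancy undefined: both k_on*c and k_off are zero.",
          class = "dybe_argument_error")
  }
  konc / (konc + koff)
}

#' Binder occupancy in a classical label-then-wash experiment
#'
#' In classical DNA-PAINT the binder is incubated for `t_label`, unbound
#' binder is washed out (solution concentration drops to zero), and
#' acquisition starts.  Occupancy relaxes toward equilibrium during
#' labeling and then decays as bound binders dissociate:
#' \deqn{f(t) = f_{occ}\,(1 - e^{-(k_{on}c + k_{off}) t_{label}})\,
#'       e^{-k_{off} t_{acq}}.}
#'
#' @inheritParams steady_state_occupancy
#' @param t_label labeling incubation time (s); `Inf` for full
#'   equilibration.
#' @param t_acq time since the wash / start of acquisition (s).
#' @return Occupied fraction in \[0, 1\]; increasing in `t_label`,
#'   decreasing in `t_acq`.
#' @export
classical_occupancy <- function(model, t_label, t_acq = 0) {
  stopifnot(inherits(model, "kinetic_model"))
  if (any(t_label < 0) || any(t_acq < 0)) {
    abort("`t_label` and `t_acq` must be nonnegative.",
          class = "dybe_argument_error")
  }
  konc <- model$k_on_binder * model$c_binder
  koff <- model$k_off_binder
  focc <- steady_state_occupancy(model)
  equil <- ifelse(is.infinite(t_label), 1, 1 - exp(-(konc + koff) * t_label))
  focc * equil * exp(-koff * t_acq)
}

#' Expected imager-binding event rate per target site
#'
#' The observed blinking rate convolves the binder-target sampling kinetics
#' with the imager hybridization kinetics.  In the fast-averaging limit the
#' per-site event rate is the occupancy-weighted imager on-rate,
#' `f_occ * k_on_imager * c_imager`.
#'
#' @inheritParams steady_state_occupancy
#' @return Expected bright events per second per site.
#' @export
expected_event_rate <- function(model) {
  steady_state_occupancy(model) * model$k_on_imager * model$c_imager
}

#' Simulate the blink trace of a single target site
#'
#' Event-driven (Gillespie-style) simulation of the nested two-state
#' process: the binder alternates unbound/bound with exponential dwells;
#' while bound, the docking strand alternates dark/bright with the imager
#' rates.  A bright interval is truncated when the binder unbinds (the
#' departing binder carries any bound imager).  In `classical` mode the
#' initial occupancy is a Bernoulli draw from
#' `classical_occupancy(model, t_label, 0)` and the binder never rebinds;
#' in `dybe` mode the initial state is stationary and rebinding continues
#' throughout.
#'
#' @inheritParams steady_state_occupancy
#' @param duration simulated time (s).
#' @param mode `"dybe"` or `"classical"`.
#' @param t_label labeling incubation time before the wash (s, classical
#'   mode only).
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return An object of class `site_trace`: a list with tibbles
#'   `binder_intervals` and `bright_intervals` (columns `t_start`, `t_end`,
#'   and for bright intervals the owning `binder` interval index),
#'   `total_duration`, and `mode`.
#' @examples
#' tr <- simulate_site_trace(kinetic_model(), duration = 200, seed = 1)
#' bound_time_fraction(tr)
#' @export
simulate_site_trace <- function(model, duration, mode = c("dybe", "classical"),
                                t_label = 3600, seed = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  mode <- match.arg(mode)
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be > 0.", class = "dybe_argument_error")
  }
  konc_b <- model$k_on_binder * model$c_binder
  res <- with_seed(seed, {
    if (mode == "dybe") {
      init <- runif(1) < steady_state_occupancy(model)
      cpp_site_trace(konc_b, model$k_off_binder,
                     model$k_on_imager * model$c_imager, model$k_off_imager,
                     duration, init, TRUE)
    } else {
      init <- runif(1) < classical_occupancy(model, t_label, 0)
      cpp_site_trace(konc_b, model$k_off_binder,
                     model$k_on_imager * model$c_imager, model$k_off_imager,
                     duration, init, FALSE)
    }
  })
  structure(list(
    binder_intervals = tibble(t_start = res$binder_start,
                              t_end = res$binder_end),
    bright_intervals = tibble(t_start = res$bright_start,
                              t_end = res$bright_end,
                              binder = res$bright_binder),
    total_duration = duration,
    mode = mode
  ), class = "site_trace")
}

#' @export
print.site_trace <- function(x, ...) {
  cat(sprintf("<site_trace> mode=%s, T=%.4g s: %d binder interval(s), %d bright interval(s)\n",
              x$mode, x$total_duration, nrow(x$binder_intervals),
              nrow(x$bright_intervals)))
  cat(sprintf("  bound-time fraction %.4g\n", bound_time_fraction(x)))
  invisible(x)
}

#' Fraction of time the target carried a binder
#'
#' @param trace a [simulate_site_trace()] result.
#' @return Bound-time fraction in \[0, 1\]; converges to
#'   [steady_state_occupancy()] for long DyBE traces.
#' @export
bound_time_fraction <- function(trace) {
  stopifnot(inherits(trace, "site_trace"))
  sum(trace$binder_intervals$t_end - trace$binder_intervals$t_start) /
    trace$total_duration
}

#' Monte Carlo detection probability of target sites
#'
#' A site counts as detected when at least one bright interval of duration
#' `>= acq$min_on_time` occurs within the acquisition window
#' `n_frames * frame_time`.  DyBE and classical modes are simulated from
#' one coupled trajectory per site (classical detection is restricted to
#' the initial binder dwell and gated by the labeling-equilibration
#' probability), so with a shared seed the classical estimate never exceeds
#' the DyBE estimate.
#'
#' @inheritParams simulate_site_trace
#' @param acq an [acquisition_settings()].
#' @param n_sites number of simulated sites.
#' @return A one-row tibble (class `detection_summary`) with `mode`,
#'   `n_sites`, `n_detected`, `detection_probability`, and Clopper-Pearson
#'   95% bounds `ci_lo`, `ci_hi`.  `mode = "both"` returns two rows from
#'   the same coupled trajectories.
#' @examples
#' detection_probability(kinetic_model(),
#'                       acquisition_settings(n_frames = 2000),
#'                       mode = "both", n_sites = 500, seed = 7)
#' @export
detection_probability <- function(model, acq, mode = c("dybe", "classical", "both"),
                                  t_label = 3600, n_sites = 1000, seed = NULL) {
  stopifnot(inherits(model, "kinetic_model"),
            inherits(acq, "acquisition_settings"))
  mode <- match.arg(mode)
  if (!is.numeric(n_sites) || n_sites < 1) {
    abort("`n_sites` must be >= 1.", class = "dybe_argument_error")
  }
  if (t_label < 0) abort("`t_label` must be >= 0.", class = "dybe_argument_error")
  n_sites <- as.integer(n_sites)
  konc_b <- model$k_on_binder * model$c_binder
  koff_b <- model$k_off_binder
  duration <- acq$n_frames * acq$frame_time
  p_label <- if (is.infinite(t_label)) 1 else 1 - exp(-(konc_b + koff_b) * t_label)
  counts <- with_seed(seed, {
    cpp_detect_batch(n_sites, konc_b, koff_b,
                     model$k_on_imager * model$c_imager, model$k_off_imager,
                     duration, acq$min_on_time, p_label)
  })
  modes <- if (mode == "both") c("dybe", "classical") else mode
  out <- purrr::map_dfr(modes, function(m) {
    k <- counts[[m]]
    ci <- stats::binom.test(k, n_sites)$conf.int
    tibble(mode = m, n_sites = n_sites, n_detected = k,
           detection_probability = k / n_sites,
           ci_lo = ci[1], ci_hi = ci[2])
  })
  class(out) <- c("detection_summary", class(out))
  out
}
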