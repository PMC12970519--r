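# Synthetic ground truth and localization rendering.
#
# Geometry is 2D (membrane receptors in TIRF) with periodic (torus)
# boundaries: complex seed points are a homogeneous Poisson process, dimer
# partners sit at exactly `dimer_distance` with uniform random orientation,
# and every downstream coordinate is wrapped back into the field.

#' Generate a ground-truth protein map
#'
#' Draws a homogeneous Poisson number of protein complexes at the mixture's
#' density, places each complex uniformly in the field, assigns species by
#' the mixture fractions, and expands dimers into two proteins separated by
#' `dimer_distance` at a uniform random orientation (wrapped on the torus).
#'
#' @param mix a [species_mix()].
#' @param field field geometry (an [acquisition_settings()] or
#'   `list(width, height)` in nm).
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return A tibble of class `ground_truth_map` with one row per protein:
#'   `x`, `y` (nm), `channel` (`"A"`/`"B"`), `complex_id`, `species`.
#'   The field geometry is kept in the `"field"` attribute.
#' @examples
#' gt <- generate_ground_truth(species_mix(c(homo_AA = 1), density = 5),
#'                             list(width = 5000, height = 5000), seed = 1)
#' table(gt$species)
#' @export
generate_ground_truth <- function(mix, field, seed = NULL) {
  stopifnot(inherits(mix, "species_mix"))
  f <- as_field(field)
  area <- field_area_um2(f)
  if (area <= 0) abort("field area must be positive.",
                       class = "dybe_argument_error")
  with_seed(seed, {
    n_complex <- rpois(1, mix$density * area)
    if (n_complex == 0) {
      out <- tibble(x = numeric(0), y = numeric(0),
                    channel = character(0), complex_id = integer(0),
                    species = character(0))
    } else {
      species <- sample(names(mix$fractions), n_complex, replace = TRUE,
                        prob = mix$fractions)
      cx <- runif(n_complex, 0, f$width)
      cy <- runif(n_complex, 0, f$height)
      is_dimer <- species %in% c("homo_AA", "homo_BB", "hetero_AB")
      theta <- runif(n_complex, 0, 2 * pi)
      first_channel <- ifelse(species %in% c("mono_B", "homo_BB"), "B", "A")
      out <- tibble(x = cx, y = cy, channel = first_channel,
                    complex_id = seq_len(n_complex), species = species)
      if (any(is_dimer)) {
        partner_channel <- c(homo_AA = "A", homo_BB = "B", hetero_AB = "B")
        d <- mix$dimer_distance
        partners <- tibble(
          x = wrap_coord(cx[is_dimer] + d * cos(theta[is_dimer]), f$width),
          y = wrap_coord(cy[is_dimer] + d * sin(theta[is_dimer]), f$height),
          channel = unname(partner_channel[species[is_dimer]]),
          complex_id = out$complex_id[is_dimer],
          species = species[is_dimer])
        out <- bind_rows(out, partners) %>% arrange(.data$complex_id)
      }
    }
    attr(out, "field") <- f
    attr(out, "mix") <- mix
    class(out) <- c("ground_truth_map", class(out))
    out
  })
}

#' Thin a ground-truth map by labeling efficiency
#'
#' Independent per-protein Bernoulli thinning: each protein survives with
#' probability `labeling_efficiency`, emulating incomplete labeling.
#' Complex membership metadata is preserved on the survivors.
#'
#' @param gt a [generate_ground_truth()] map.
#' @param labeling_efficiency survival probability in \[0, 1\].  A named
#'   vector `c(A = ..., B = ...)` applies per-channel efficiencies.
#' @inheritParams generate_ground_truth
#' @return The thinned `ground_truth_map`.
#' @export
apply_labeling <- function(gt, labeling_efficiency, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth_map"))
  le <- labeling_efficiency
  if (!is.null(names(le)) && all(c("A", "B") %in% names(le))) {
    check_fraction(le[["A"]], "labeling_efficiency[A]")
    check_fraction(le[["B"]], "labeling_efficiency[B]")
    p <- unname(le[gt$channel])
  } else {
    check_fraction(le, "labeling_efficiency")
    p <- rep(le, nrow(gt))
  }
  with_seed(seed, {
    keep <- runif(nrow(gt)) < p
    out <- gt[keep, , drop = FALSE]
    attr(out, "field") <- attr(gt, "field")
    attr(out, "mix") <- attr(gt, "mix")
    class(out) <- class(gt)
    out
  })
}

# expand bright intervals into per-frame localization rows
frames_covered <- function(t_start, t_end, frame_time, min_on, n_frames) {
  first <- floor(t_start / frame_time)
  last <- pmin(floor((t_end - 1e-12) / frame_time), n_frames - 1)
  nrep <- pmax(0L, as.integer(last - first + 1))
  iv <- rep.int(seq_along(t_start), nrep)
  frame <- unlist(lapply(seq_along(t_start), function(i) {
    if (nrep[i] <= 0) integer(0) else seq.int(first[i], last[i])
  }), use.names = FALSE)
  if (length(frame) == 0) {
    return(list(interval = integer(0), frame = integer(0)))
  }
  overlap <- pmin(t_end[iv], (frame + 1) * frame_time) -
    pmax(t_start[iv], frame * frame_time)
  # tolerate float cancellation at frame boundaries (e.g. 1.3 - 1.2 < 0.1)
  keep <- overlap >= min_on - 1e-9 * frame_time
  list(interval = iv[keep], frame = as.integer(frame[keep]))
}

#' Render blinking localizations from a labeled ground-truth map
#'
#' For every labeled protein, simulates a dual-kinetic blink trace
#' ([simulate_site_trace()] semantics, batched) and emits one localization
#' record per camera frame that a bright interval covers for at least
#' `min_on_time`.  Localizations sit at the protein position plus a fixed-
#' length linkage offset whose direction is resampled for every binder
#' binding event, plus isotropic Gaussian localization error `sigma_loc`
#' per record; coordinates are wrapped on the torus field.
#'
#' @inheritParams apply_labeling
#' @param model a [kinetic_model()].
#' @param acq an [acquisition_settings()].
#' @param mode `"dybe"` or `"classical"`.
#' @param t_label labeling incubation time (s, classical mode).
#' @return A tibble of class `localization_table` with columns `frame`
#'   (0-based), `x`, `y` (nm), `sigma` (nm), `channel`, `origin`
#'   (`"specific"`), and `protein_id` (row index into `gt`, kept for
#'   validation against ground truth).  Acquisition settings are stored in
#'   the `"acq"` attribute.
#' @export
simulate_localizations <- function(gt, model, acq,
                                   mode = c("dybe", "classical"),
                                   t_label = 3600, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth_map"),
            inherits(model, "kinetic_model"),
            inherits(acq, "acquisition_settings"))
  mode <- match.arg(mode)
  f <- as_field(acq)
  duration <- acq$n_frames * acq$frame_time
  konc_b <- model$k_on_binder * model$c_binder
  init_prob <- if (mode == "dybe") {
    if (konc_b + model$k_off_binder > 0) steady_state_occupancy(model) else 0
  } else {
    classical_occupancy(model, t_label, 0)
  }
  with_seed(seed, {
    res <- cpp_bright_batch(nrow(gt), konc_b, model$k_off_binder,
                            model$k_on_imager * model$c_imager,
                            model$k_off_imager, duration, init_prob,
                            mode == "dybe")
    cov <- frames_covered(res$t_start, res$t_end, acq$frame_time,
                          acq$min_on_time, acq$n_frames)
    iv <- cov$interval
    if (length(iv) == 0) {
      out <- empty_loc_table()
    } else {
      site <- res$site[iv]
      # one linkage-offset direction per (site, binder event)
      ev_key <- paste(res$site, res$binder)
      ev_levels <- unique(ev_key)
      theta <- runif(length(ev_levels), 0, 2 * pi)
      ev <- match(ev_key[iv], ev_levels)
      n <- length(iv)
      x <- gt$x[site] + acq$linkage_offset * cos(theta[ev]) +
        rnorm(n, 0, acq$sigma_loc)
      y <- gt$y[site] + acq$linkage_offset * sin(theta[ev]) +
        rnorm(n, 0, acq$sigma_loc)
      out <- tibble(frame = cov$frame,
                    x = wrap_coord(x, f$width),
                    y = wrap_coord(y, f$height),
                    sigma = rep(max(acq$sigma_loc, .Machine$double.eps), n),
                    channel = gt$channel[site],
                    origin = "specific",
                    protein_id = site) %>%
        arrange(.data$frame, .data$protein_id)
    }
    attr(out, "acq") <- acq
    class(out) <- c("localization_table", class(out))
    out
  })
}

empty_loc_table <- function() {
  tibble(frame = integer(0), x = numeric(0), y = numeric(0),
         sigma = numeric(0), channel = character(0), origin = character(0),
         protein_id = integer(0))
}

#' Add complete-spatial-randomness background localizations
#'
#' Appends nonspecific events: a Poisson number of records
#' (`density * area * n_frames / 1000` on average), positioned uniformly in
#' the field, assigned uniform random frames, and flagged
#' `origin = "background"`.  Each background event yields one localization.
#'
#' @param table a [simulate_localizations()] table.
#' @param background_density events per square micrometer per 1000 frames.
#' @param field field geometry; defaults to the table's acquisition
#'   settings.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @param channel channel label for the background records; defaults to the
#'   table's (unique) channel, or `"A"` for an empty table.
#' @return The augmented `localization_table`.
#' @export
add_nonspecific <- function(table, background_density, field = NULL,
                            seed = NULL, channel = NULL) {
  stopifnot(inherits(table, "localization_table"))
  check_nonneg(background_density, "background_density")
  acq <- attr(table, "acq")
  if (is.null(field)) field <- acq
  f <- as_field(field)
  n_frames <- if (!is.null(acq)) acq$n_frames else max(table$frame, 0L) + 1L
  sigma <- if (!is.null(acq)) acq$sigma_loc else stats::median(table$sigma)
  if (is.null(channel)) {
    channel <- if (nrow(table) > 0) unique(table$channel)[1] else "A"
  }
  with_seed(seed, {
    lambda <- background_density * field_area_um2(f) * n_frames / 1000
    n_bg <- rpois(1, lambda)
    if (n_bg > 0) {
      bg <- tibble(frame = as.integer(floor(runif(n_bg, 0, n_frames))),
                   x = runif(n_bg, 0, f$width),
                   y = runif(n_bg, 0, f$height),
                   sigma = rep(max(sigma, .Machine$double.eps), n_bg),
                   channel = channel, origin = "background",
                   protein_id = NA_integer_)
      out <- bind_rows(as_tibble(table), bg)
    } else {
      out <- as_tibble(table)
    }
    attr(out, "acq") <- acq
    class(out) <- c("localization_table", class(out))
    out
  })
}
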