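#' Two-layer binding kinetics of a DyBE experiment
#'
#' Bundles the six rate/concentration parameters of the two coupled kinetic
#' layers: the reversible binder-target interaction (layer 1) and the
#' transient imager-docking hybridization on the binder's DNA handle
#' (layer 2).  Solution concentrations are assumed constant (pseudo-first-
#' order kinetics, no depletion), so only the products `k_on * c` enter the
#' dynamics.
#'
#' Defaults describe a typical high-off-rate nanobody under optimized
#' dynamic-binder-exchange conditions: binder at 20 nM with
#' `k_on = 1e-3 /nM/s` and `k_off = 0.08 /s` (equilibrium occupancy 0.2),
#' and a standard DNA-PAINT imager (`k_on = 6e-3 /nM/s`, 1 nM,
#' `k_off = 2 /s`, i.e. mean bright time 0.5 s).
#'
#' @param k_on_binder binder association rate constant (per nM per s).
#' @param c_binder solution binder concentration (nM).
#' @param k_off_binder binder dissociation rate (per s).
#' @param k_on_imager imager association rate constant (per nM per s).
#' @param c_imager imager concentration (nM).
#' @param k_off_imager imager dissociation rate (per s).
#' @return An object of class `kinetic_model` (a named list of the six
#'   parameters).
#' @examples
#' m <- kinetic_model()
#' steady_state_occupancy(m)
#' @export
kinetic_model <- function(k_on_binder = 1e-3, c_binder = 20,
                          k_off_binder = 0.08,
                          k_on_imager = 6e-3, c_imager = 1,
                          k_off_imager = 2) {
  vals <- list(k_on_binder = k_on_binder, c_binder = c_binder,
               k_off_binder = k_off_binder, k_on_imager = k_on_imager,
               c_imager = c_imager, k_off_imager = k_off_imager)
  for (nm in names(vals)) check_nonneg(vals[[nm]], nm)
  if (!is.finite(k_on_binder * c_binder) || !is.finite(k_on_imager * c_imager)) {
    abort("pseudo-first-order products k_on * c must be finite.",
          class = "dybe_argument_error")
  }
  structure(vals, class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model>\n")
  cat(sprintf("  binder: k_on %.3g /nM/s x %.3g nM (k_on*c = %.3g /s), k_off %.3g /s\n",
              x$k_on_binder, x$c_binder, x$k_on_binder * x$c_binder,
              x$k_off_binder))
  cat(sprintf("  imager: k_on %.3g /nM/s x %.3g nM (k_on*c = %.3g /s), k_off %.3g /s\n",
              x$k_on_imager, x$c_imager, x$k_on_imager * x$c_imager,
              x$k_off_imager))
  occ <- try(steady_state_occupancy(x), silent = TRUE)
  if (!inherits(occ, "try-error")) {
    cat(sprintf("  equilibrium binder occupancy: %.3g\n", occ))
  }
  invisible(x)
}

#' Acquisition geometry and detection settings
#'
#' Describes how blink traces are turned into localization records: camera
#' frame timing, the minimum bright duration for a localization, the
#' localization precision, the binder-geometry linkage offset, and the field
#' of view.
#'
#' @param frame_time camera frame time (s).
#' @param n_frames number of acquired frames.
#' @param min_on_time minimum bright duration within a frame for a
#'   localization to be emitted (s); defaults to one frame time.
#' @param sigma_loc isotropic localization precision (nm, standard
#'   deviation per axis).
#' @param linkage_offset fixed binder-geometry offset length (nm); the
#'   offset direction is resampled for every binder binding event.
#' @param field_width,field_height field of view (nm).
#' @param pixel_size camera pixel size (nm), used for HDF5 export.
#' @return An object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(frame_time = 0.1, n_frames = 10000,
                                 min_on_time = frame_time, sigma_loc = 5,
                                 linkage_offset = 0,
                                 field_width = 20000, field_height = 20000,
                                 pixel_size = 130) {
  if (!is.numeric(frame_time) || frame_time <= 0) {
    abort("`frame_time` must be > 0.", class = "dybe_argument_error")
  }
  if (!is.numeric(n_frames) || n_frames < 1) {
    abort("`n_frames` must be >= 1.", class = "dybe_argument_error")
  }
  if (!is.numeric(min_on_time) || min_on_time <= 0 || min_on_time > frame_time) {
    abort("`min_on_time` must satisfy 0 < min_on_time <= frame_time.",
          class = "dybe_argument_error")
  }
  check_nonneg(sigma_loc, "sigma_loc")
  check_nonneg(linkage_offset, "linkage_offset")
  for (nm in c("field_width", "field_height", "pixel_size")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) {
      abort(sprintf("`%s` must be > 0.", nm), class = "dybe_argument_error")
    }
  }
  structure(list(frame_time = frame_time, n_frames = as.integer(n_frames),
                 min_on_time = min_on_time, sigma_loc = sigma_loc,
                 linkage_offset = linkage_offset,
                 field_width = field_width, field_height = field_height,
                 pixel_size = pixel_size),
            class = "acquisition_settings")
}

#' @export
print.acquisition_settings <- function(x, ...) {
  cat("<acquisition_settings>\n")
  cat(sprintf("  %d frames x %.3g s (T = %.4g s), min bright time %.3g s\n",
              x$n_frames, x$frame_time, x$n_frames * x$frame_time,
              x$min_on_time))
  cat(sprintf("  sigma_loc %.3g nm, linkage offset %.3g nm\n",
              x$sigma_loc, x$linkage_offset))
  cat(sprintf("  field %.4g x %.4g nm, pixel %.3g nm\n",
              x$field_width, x$field_height, x$pixel_size))
  invisible(x)
}

# canonical species vocabulary
.dybe_species <- c("mono_A", "mono_B", "homo_AA", "homo_BB", "hetero_AB")
.dybe_species_sym <- c("mono", "homo", "hetero")

# molecules contributed to each channel by one complex of each species
.species_channels <- list(
  mono_A   = c(A = 1L, B = 0L),
  mono_B   = c(A = 0L, B = 1L),
  homo_AA  = c(A = 2L, B = 0L),
  homo_BB  = c(A = 0L, B = 2L),
  hetero_AB = c(A = 1L, B = 1L)
)

# Expand symmetric shorthand ("mono", "homo", "hetero") to the five
# channelled species with equal A/B split.
expand_species_fractions <- function(fractions) {
  if (is.null(names(fractions)) || any(names(fractions) == "")) {
    abort("`fractions` must be a named vector of species fractions.",
          class = "dybe_argument_error")
  }
  unknown <- setdiff(names(fractions), c(.dybe_species, .dybe_species_sym))
  if (length(unknown) > 0) {
    abort(sprintf("unknown species: %s", paste(unknown, collapse = ", ")),
          class = "dybe_argument_error")
  }
  out <- setNames(numeric(length(.dybe_species)), .dybe_species)
  for (nm in names(fractions)) {
    v <- fractions[[nm]]
    if (nm == "mono") {
      out["mono_A"] <- out["mono_A"] + v / 2
      out["mono_B"] <- out["mono_B"] + v / 2
    } else if (nm == "homo") {
      out["homo_AA"] <- out["homo_AA"] + v / 2
      out["homo_BB"] <- out["homo_BB"] + v / 2
    } else if (nm == "hetero") {
      out["hetero_AB"] <- out["hetero_AB"] + v
    } else {
      out[nm] <- out[nm] + v
    }
  }
  out
}

#' Composition of a two-channel protein-complex mixture
#'
#' Describes the ground truth that the synthetic-data generator draws from:
#' the fractions of complexes that are channel-A/B monomers, homodimers or
#' A-B heterodimers, the intra-dimer distance, and the areal density of
#' complexes.
#'
#' Species names are `mono_A`, `mono_B`, `homo_AA`, `homo_BB`, `hetero_AB`;
#' the symmetric shorthand `mono`, `homo`, `hetero` is also accepted and
#' splits equally between the two channels.
#'
#' @param fractions named numeric vector of species fractions (must be
#'   nonnegative and sum to 1).
#' @param dimer_distance separation of dimer partners (nm).
#' @param density complexes per square micrometer.
#' @return An object of class `species_mix`.
#' @examples
#' species_mix(c(mono = 0.5, homo = 0.3, hetero = 0.2))
#' @export
species_mix <- function(fractions = c(mono_A = 1), dimer_distance = 15,
                        density = 50) {
  fr <- expand_species_fractions(fractions)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    abort("species fractions must be nonnegative and sum to 1.",
          class = "dybe_argument_error")
  }
  if (!is.numeric(dimer_distance) || dimer_distance <= 0) {
    abort("`dimer_distance` must be > 0 (nm).",
          class = "dybe_argument_error")
  }
  check_nonneg(density, "density")
  structure(list(fractions = fr, dimer_distance = dimer_distance,
                 density = density),
            class = "species_mix")
}

#' @export
print.species_mix <- function(x, ...) {
  cat("<species_mix>\n")
  nz <- x$fractions[x$fractions > 0]
  cat("  fractions:", paste(sprintf("%s=%.3g", names(nz), nz), collapse = ", "),
      "\n")
  cat(sprintf("  dimer distance %.3g nm, density %.3g complexes/um^2\n",
              x$dimer_distance, x$density))
  invisible(x)
}
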