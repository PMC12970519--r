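# internal helpers shared across modules

# Run code under a fixed seed without disturbing the caller's RNG state.
# seed = NULL means "use the current stream" (still reproducible when the
# caller seeded it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

# Coerce anything field-like (acquisition_settings, or a list/vector with
# width/height in nm) to list(width, height).
as_field <- function(x) {
  if (inherits(x, "acquisition_settings")) {
    return(list(width = x$field_width, height = x$field_height))
  }
  x <- as.list(x)
  if (!is.null(x$field_width)) {
    f <- list(width = x$field_width, height = x$field_height)
  } else {
    f <- list(width = x$width, height = x$height)
  }
  if (is.null(f$width) || is.null(f$height) ||
      !is.finite(f$width) || !is.finite(f$height) ||
      f$width <= 0 || f$height <= 0) {
    abort("`field` must provide positive width and height (nm).",
          class = "dybe_argument_error")
  }
  f
}

field_area_um2 <- function(field) {
  f <- as_field(field)
  f$width * f$height / 1e6
}

# Per-axis minimum-image (torus) distance between matched rows of two
# 2-column coordinate sets.  The brute-force test oracle uses the same
# formula, so agreement on neighbor identity implies bitwise-equal distances.
torus_dist <- function(x1, y1, x2, y2, width, height) {
  dx <- abs(x1 - x2)
  dx <- pmin(dx, width - dx)
  dy <- abs(y1 - y2)
  dy <- pmin(dy, height - dy)
  sqrt(dx * dx + dy * dy)
}

wrap_coord <- function(x, extent) {
  x - extent * floor(x / extent)
}

# Extract an n x 2 coordinate matrix from a points argument (tibble/data
# frame with x, y columns, or a 2-column matrix).
as_xy <- function(points, arg = "points") {
  if (is.matrix(points)) {
    if (ncol(points) < 2) {
      abort(sprintf("`%s` must have two coordinate columns.", arg),
            class = "dybe_argument_error")
    }
    m <- points[, 1:2, drop = FALSE]
  } else {
    points <- as.data.frame(points)
    if (!all(c("x", "y") %in% names(points))) {
      abort(sprintf("`%s` must have `x` and `y` columns (nm).", arg),
            class = "dybe_argument_error")
    }
    m <- cbind(points$x, points$y)
  }
  storage.mode(m) <- "double"
  if (nrow(m) > 0 && any(!is.finite(m))) {
    abort(sprintf("`%s` contains non-finite coordinates.", arg),
          class = "dybe_format_error")
  }
  m
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name),
          class = "dybe_argument_error")
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single nonnegative number.", name),
          class = "dybe_argument_error")
  }
  invisible(x)
}
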