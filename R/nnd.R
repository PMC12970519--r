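# Nearest-neighbor-distance statistics and the CSR reference.
#
# Neighbor identification uses a kd-tree (RANN); distances are then
# recomputed from the coordinates with the same per-axis minimum-image
# formula as a brute-force all-pairs scan, so the two routes agree exactly
# whenever they pick the same neighbor.

# Tile a point set over the 3x3 torus images.  Returns list(xy, orig_index).
tile_torus <- function(xy, field) {
  f <- as_field(field)
  offs <- expand.grid(ox = c(-1, 0, 1) * f$width, oy = c(-1, 0, 1) * f$height)
  n <- nrow(xy)
  tiled <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
    cbind(xy[, 1] + offs$ox[i], xy[, 2] + offs$oy[i])
  }))
  list(xy = tiled, orig = rep(seq_len(n), times = nrow(offs)))
}

# neighbor indices (into reference rows) of the k nearest reference points
# for each query row; skip_self drops one zero-distance self match.
nn_indices <- function(query, reference, k, metric, field, skip_self) {
  extra <- if (skip_self) 1L else 0L
  if (metric == "torus") {
    t0 <- tile_torus(reference, field)
    res <- RANN::nn2(data = t0$xy, query = query, k = k + extra)
    idx <- matrix(t0$orig[res$nn.idx], nrow = nrow(query))
  } else {
    res <- RANN::nn2(data = reference, query = query, k = k + extra)
    idx <- res$nn.idx
  }
  if (skip_self) idx <- idx[, -1, drop = FALSE]
  idx
}

nn_distance <- function(query, reference, idx_col, metric, field) {
  ref <- reference[idx_col, , drop = FALSE]
  if (metric == "torus") {
    f <- as_field(field)
    torus_dist(query[, 1], query[, 2], ref[, 1], ref[, 2], f$width, f$height)
  } else {
    dx <- query[, 1] - ref[, 1]
    dy <- query[, 2] - ref[, 2]
    sqrt(dx * dx + dy * dy)
  }
}

#' k-th nearest-neighbor distances within one point set
#'
#' For every point, the distance to its k-th nearest other point.  With
#' `metric = "torus"` distances use the minimum-image convention on the
#' periodic field (the convention of the synthetic generator); with
#' `metric = "euclidean"`, query points closer than `border_margin` to a
#' field edge are dropped to avoid edge bias and plain Euclidean distances
#' are returned.
#'
#' @param points tibble/data frame with `x`, `y` columns (nm), or a
#'   two-column matrix.
#' @param k neighbor order (1 = first nearest neighbor).
#' @param metric `"torus"` or `"euclidean"`.
#' @param field field geometry (an [acquisition_settings()] or
#'   `list(width, height)` in nm); required for `"torus"` and for a
#'   positive `border_margin`.
#' @param border_margin edge-exclusion margin (nm, euclidean metric only).
#' @return Numeric vector of distances (nm), one per retained query point.
#' @examples
#' pts <- tibble::tibble(x = c(0, 1, 3), y = c(0, 0, 0))
#' kth_nnd(pts, k = 1, metric = "euclidean")  # 1, 1, 2
#' @export
kth_nnd <- function(points, k = 1, metric = c("torus", "euclidean"),
                    field = NULL, border_margin = 0) {
  metric <- match.arg(metric)
  xy <- as_xy(points)
  if (nrow(xy) < k + 1) {
    abort(sprintf("need at least k + 1 = %d points.", k + 1),
          class = "dybe_argument_error")
  }
  query <- xy
  keep <- rep(TRUE, nrow(xy))
  if (metric == "euclidean" && border_margin > 0) {
    f <- as_field(field)
    keep <- xy[, 1] >= border_margin & xy[, 1] <= f$width - border_margin &
      xy[, 2] >= border_margin & xy[, 2] <= f$height - border_margin
    query <- xy[keep, , drop = FALSE]
    if (nrow(query) == 0) return(numeric(0))
  }
  idx <- nn_indices(query, xy, k, metric, field, skip_self = TRUE)
  nn_distance(query, xy, idx[, k], metric, field)
}

#' Cross nearest-neighbor distances between two point sets
#'
#' For every query point (e.g. a reference-tag protein position), the
#' distance to the nearest point of the other set (e.g. detected target
#' signals).  No self-exclusion is applied: the sets are distinct by
#' construction.
#'
#' @param query_points,reference_points point sets with `x`, `y` columns
#'   (nm).
#' @inheritParams kth_nnd
#' @return Numeric vector of distances (nm), one per retained query point.
#' @export
cross_nnd <- function(query_points, reference_points,
                      metric = c("torus", "euclidean"), field = NULL,
                      border_margin = 0) {
  metric <- match.arg(metric)
  q <- as_xy(query_points, "query_points")
  r <- as_xy(reference_points, "reference_points")
  if (nrow(r) == 0) {
    abort("`reference_points` must be non-empty.",
          class = "dybe_argument_error")
  }
  if (nrow(q) == 0) return(numeric(0))
  if (metric == "euclidean" && border_margin > 0) {
    f <- as_field(field)
    keep <- q[, 1] >= border_margin & q[, 1] <= f$width - border_margin &
      q[, 2] >= border_margin & q[, 2] <= f$height - border_margin
    q <- q[keep, , drop = FALSE]
    if (nrow(q) == 0) return(numeric(0))
  }
  idx <- nn_indices(q, r, 1, metric, field, skip_self = FALSE)
  nn_distance(q, r, idx[, 1], metric, field)
}

#' CSR nearest-neighbor-distance CDF
#'
#' Cumulative distribution of the k-th nearest-neighbor distance for a
#' homogeneous planar Poisson process of intensity `rho`: the k-th neighbor
#' lies within `r` unless the disc of radius `r` holds fewer than `k`
#' points, so
#' \deqn{F_k(r) = 1 - \sum_{j=0}^{k-1} e^{-\rho\pi r^2}
#'       \frac{(\rho\pi r^2)^j}{j!}.}
#' For `k = 1` this is the classical \eqn{1 - e^{-\rho\pi r^2}}.
#'
#' @param rho intensity (points per nm^2).
#' @param r distance(s) at which to evaluate (nm).
#' @param k neighbor order.
#' @return Probabilities in \[0, 1\], nondecreasing in `r`.
#' @examples
#' rho <- 50e-6                       # 50 points per um^2
#' csr_nnd_cdf(rho, sqrt(log(2) / (pi * rho)))  # median: 0.5
#' @export
csr_nnd_cdf <- function(rho, r, k = 1) {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0) {
    abort("`rho` must be a single positive intensity (points per nm^2).",
          class = "dybe_argument_error")
  }
  if (any(r < 0)) abort("`r` must be >= 0.", class = "dybe_argument_error")
  ppois(k - 1, rho * pi * r^2, lower.tail = FALSE)
}

#' Histogram of nearest-neighbor distances with a CSR overlay
#'
#' Bins distances into a probability density (normalized by the total
#' sample count and the bin width, so the histogram integrates to at most
#' one over the binned range) and, when the point intensity is known,
#' tabulates the CSR density expected at that intensity.
#'
#' @param distances numeric vector of NNDs (nm).
#' @param bin_edges increasing vector of bin edges (nm).  The default is
#'   5 nm bins over 0-200 nm, the receptor scale.
#' @param rho optional intensity (points per nm^2) for the CSR reference;
#'   typically point count / field area.
#' @param k neighbor order used for the CSR reference.
#' @return A tibble of class `nnd_result` with columns `bin_lo`, `bin_hi`,
#'   `density` and `csr_density` (NA without `rho`); the raw distances,
#'   `k` and `rho` are kept as attributes.
#' @export
nnd_histogram <- function(distances, bin_edges = seq(0, 200, by = 5),
                          rho = NULL, k = 1) {
  if (length(distances) == 0) {
    abort("`distances` must be non-empty.", class = "dybe_argument_error")
  }
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    abort("`bin_edges` must be increasing.", class = "dybe_argument_error")
  }
  widths <- diff(bin_edges)
  nb <- length(widths)
  idx <- findInterval(distances, bin_edges)  # [lo, hi) bins; beyond-range -> 0 or nb+1
  counts <- tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  dens <- counts / (length(distances) * widths)
  csr <- rep(NA_real_, length(widths))
  if (!is.null(rho)) {
    cdf <- csr_nnd_cdf(rho, bin_edges, k = k)
    csr <- diff(cdf) / widths
  }
  out <- tibble(bin_lo = bin_edges[-length(bin_edges)],
                bin_hi = bin_edges[-1],
                density = dens, csr_density = csr)
  attr(out, "distances") <- distances
  attr(out, "k") <- k
  attr(out, "rho") <- rho
  class(out) <- c("nnd_result", class(out))
  out
}

#' Write an NND histogram to CSV
#'
#' @param result an [nnd_histogram()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_nnd_csv <- function(result, path) {
  stopifnot(inherits(result, "nnd_result"))
  readr::write_csv(as_tibble(result)[, c("bin_lo", "bin_hi", "density",
                                         "csr_density")], path)
  invisible(path)
}
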