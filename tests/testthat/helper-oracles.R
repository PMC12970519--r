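# Independent oracles and small data generators shared across tests.

# All-pairs k-th NND oracle.  Uses the same per-axis minimum-image formula
# as the package's distance recomputation, so agreement on neighbor
# identity implies exact (bitwise) agreement on distances; the neighbor
# search itself is a full scan, independent of the kd-tree path.
oracle_pair_dist <- function(xy_q, xy_r, metric, field) {
  n_q <- nrow(xy_q)
  n_r <- nrow(xy_r)
  d <- matrix(0, n_q, n_r)
  for (i in seq_len(n_q)) {
    dx <- abs(xy_q[i, 1] - xy_r[, 1])
    dy <- abs(xy_q[i, 2] - xy_r[, 2])
    if (metric == "torus") {
      dx <- pmin(dx, field$width - dx)
      dy <- pmin(dy, field$height - dy)
    }
    d[i, ] <- sqrt(dx * dx + dy * dy)
  }
  d
}

oracle_kth_nnd <- function(xy, k, metric = "euclidean", field = NULL) {
  d <- oracle_pair_dist(xy, xy, metric, field)
  diag(d) <- Inf
  apply(d, 1, function(row) sort(row)[k])
}

oracle_cross_nnd <- function(xy_q, xy_r, metric = "euclidean", field = NULL) {
  d <- oracle_pair_dist(xy_q, xy_r, metric, field)
  apply(d, 1, min)
}

# CSR pattern with a fixed number of points
csr_points <- function(n, field) {
  tibble::tibble(x = runif(n, 0, field$width), y = runif(n, 0, field$height))
}

# reference/target pair for labeling-efficiency recovery: CSR references,
# each detected as a target with probability `le` at Gaussian-displaced
# position (the generative family the estimator assumes)
gen_le_dataset <- function(n_ref, le, sd, field, seed) {
  withr::with_seed(seed, {
    rx <- runif(n_ref, 0, field$width)
    ry <- runif(n_ref, 0, field$height)
    det <- runif(n_ref) < le
    tgt <- tibble::tibble(
      x = (rx[det] + rnorm(sum(det), 0, sd)) %% field$width,
      y = (ry[det] + rnorm(sum(det), 0, sd)) %% field$height)
    list(ref = tibble::tibble(x = rx, y = ry), tgt = tgt)
  })
}

# ground truth -> noisy detected positions per channel (no blinking), the
# input the stoichiometry fitter sees
gen_mixture_positions <- function(mix, le, sd, field, seed) {
  gt <- generate_ground_truth(mix, field, seed = seed)
  lab <- apply_labeling(gt, le, seed = seed + 1L)
  withr::with_seed(seed + 2L, {
    x <- (lab$x + rnorm(nrow(lab), 0, sd)) %% field$width
    y <- (lab$y + rnorm(nrow(lab), 0, sd)) %% field$height
  })
  pos <- tibble::tibble(x = x, y = y, channel = lab$channel)
  list(A = pos[pos$channel == "A", ], B = pos[pos$channel == "B", ])
}

test_field <- function(w = 10000, h = 10000) list(width = w, height = h)
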