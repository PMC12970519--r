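test_that("density-linkage clustering recovers isolated proteins", {
  # one protein's blinks scattered well below the linkage radius
  withr::with_seed(1, {
    one <- tibble::tibble(frame = 0:49,
                          x = 500 + rnorm(50, 0, 3),
                          y = 500 + rnorm(50, 0, 3),
                          sigma = 5, channel = "A", origin = "specific")
  })
  cl <- cluster_localizations(one, link_radius = 20, min_locs = 3)
  expect_equal(nrow(cl), 1)
  expect_lt(abs(cl$x - 500), 3)
  expect_equal(cl$n_locs, 50L)

  # two proteins ten linkage radii apart
  two <- dplyr::bind_rows(one, dplyr::mutate(one, x = x + 200))
  cl2 <- cluster_localizations(two, link_radius = 20, min_locs = 3)
  expect_equal(nrow(cl2), 2)

  # empty in, empty out
  expect_equal(nrow(cluster_localizations(one[0, ])), 0)
})

test_that("min_locs filtering removes single-blink background", {
  withr::with_seed(2, {
    tab <- dplyr::bind_rows(
      tibble::tibble(frame = 0:19, x = 100 + rnorm(20, 0, 3),
                     y = 100 + rnorm(20, 0, 3), sigma = 5,
                     channel = "A", origin = "specific"),
      tibble::tibble(frame = 0:9, x = seq(1000, 4000, length.out = 10),
                     y = seq(4000, 1000, length.out = 10), sigma = 5,
                     channel = "A", origin = "background"))
  })
  cl <- cluster_localizations(tab, link_radius = 20, min_locs = 2)
  expect_equal(nrow(cl), 1)
})

test_that("cluster counts track the labeled protein count", {
  acq <- acquisition_settings(n_frames = 20000, sigma_loc = 5,
                              field_width = 20000, field_height = 20000)
  gt <- generate_ground_truth(species_mix(c(mono_A = 1), density = 5),
                              acq, seed = 3)
  # generous blinking: ~12 events per protein, ~5 frames each
  m <- kinetic_model(1e-3, 20, 0.08, 6e-3, 5, 2)
  locs <- simulate_localizations(gt, m, acq, seed = 4)
  cl <- cluster_localizations(locs, link_radius = 25, min_locs = 3)
  expect_lt(abs(nrow(cl) - nrow(gt)) / nrow(gt), 0.05)
})

test_that("the cross-NND model family behaves at its limits", {
  f <- test_field()
  bins <- seq(0, 200, 5)
  # perfect labeling with negligible noise: all mass in the first bin
  h1 <- simulate_cross_nnd_model(50, le = 1, measurement_sd = 1e-6,
                                 ref_target_offset = 0, field = f,
                                 n_replicates = 2, seed = 5,
                                 bin_edges = bins)
  expect_equal(sum(h1$density * diff(bins)), h1$density[1] * 5)
  # sparse labeling: cross-NND approaches the CSR form at the detected-
  # target density
  le <- 0.1
  h0 <- simulate_cross_nnd_model(100, le = le, measurement_sd = 10,
                                 field = f, n_replicates = 6, seed = 6,
                                 bin_edges = bins)
  # detected references (fraction le) pair with their own target at a
  # Rayleigh-distributed distance; the remaining (1 - le) fall back to the
  # CSR background of detected targets
  rho_det <- 100 * le / 1e6  # per nm^2
  emp_cdf <- cumsum(h0$density * diff(bins))
  theo_cdf <- le * (1 - exp(-bins[-1]^2 / (2 * 10^2))) +
    (1 - le) * csr_nnd_cdf(rho_det, bins[-1])
  expect_lt(max(abs(emp_cdf - theo_cdf)), 0.01)
})

test_that("short-range model mass grows monotonically with efficiency", {
  f <- test_field()
  bins <- seq(0, 200, 5)
  mass <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(le) {
    h <- simulate_cross_nnd_model(50, le, measurement_sd = 10, field = f,
                                  n_replicates = 2, seed = 7,
                                  bin_edges = bins)
    sum(h$density[1:6] * 5)  # mass within 3 sd of the offset (0)
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("labeling-efficiency estimates recover the simulated truth", {
  f <- test_field(20000, 20000)
  for (le in c(0.05, 0.74)) {
    d <- gen_le_dataset(5000, le, 10, f, seed = round(100 * le))
    fit <- estimate_labeling_efficiency(d$ref, d$tgt, f, seed = 17,
                                        measurement_sd = 10)
    expect_lt(abs(fit$estimate - le), 0.05)
    expect_true(all(diff(fit$grid$le) > 0))
    expect_true(fit$estimate %in% fit$grid$le)
    expect_gte(min(fit$grid$objective), 0)
  }
})

test_that("perfect colocalization yields a near-unit estimate", {
  f <- test_field()
  withr::with_seed(18, pts <- csr_points(2000, f))
  fit <- estimate_labeling_efficiency(pts, pts, f, seed = 19,
                                      measurement_sd = 5)
  expect_gte(fit$estimate, 0.95)
})

test_that("estimates are invariant to global torus translation", {
  f <- test_field(20000, 20000)
  d <- gen_le_dataset(3000, 0.5, 10, f, seed = 21)
  shift <- function(p) tibble::tibble(x = (p$x + 5000) %% f$width,
                                      y = (p$y + 7000) %% f$height)
  fit1 <- estimate_labeling_efficiency(d$ref, d$tgt, f, seed = 22,
                                       measurement_sd = 10)
  fit2 <- estimate_labeling_efficiency(shift(d$ref), shift(d$tgt), f,
                                       seed = 22, measurement_sd = 10)
  expect_equal(fit1$estimate, fit2$estimate)
})

test_that("fit accessors and argument validation behave", {
  f <- test_field()
  d <- gen_le_dataset(800, 0.5, 10, f, seed = 23)
  fit <- estimate_labeling_efficiency(d$ref, d$tgt, f, seed = 24,
                                      measurement_sd = 10)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
  expect_equal(glance(fit)$estimate, fit$estimate)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_error(estimate_labeling_efficiency(d$ref[0, ], d$tgt, f, seed = 1),
               class = "dybe_argument_error")
  expect_error(estimate_labeling_efficiency(d$ref, d$tgt, f,
                                            grid_step = 0.03, seed = 1),
               class = "dybe_argument_error")
})
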