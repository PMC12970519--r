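test_that("steady-state occupancy follows the two-state equilibrium", {
  # symmetry: k_on*c == k_off
  expect_equal(steady_state_occupancy(kinetic_model(0.01, 5, 0.05)), 0.5)
  # irreversible limit
  expect_equal(steady_state_occupancy(kinetic_model(1e-3, 20, 0)), 1)
  # direct arithmetic: 0.02 / (0.02 + 0.08)
  expect_equal(steady_state_occupancy(kinetic_model(1e-3, 20, 0.08)), 0.2)
  expect_error(steady_state_occupancy(kinetic_model(0, 0, 0)),
               class = "dybe_argument_error")
})

test_that("occupancy is monotone in off-rate and binder concentration", {
  koffs <- 10^seq(-3, 0, length.out = 7)
  occ_koff <- vapply(koffs, function(k)
    steady_state_occupancy(kinetic_model(1e-3, 20, k)), numeric(1))
  expect_true(all(diff(occ_koff) < 0))
  cs <- c(1, 5, 10, 20, 50)
  occ_c <- vapply(cs, function(cc)
    steady_state_occupancy(kinetic_model(1e-3, cc, 0.08)), numeric(1))
  expect_true(all(diff(occ_c) > 0))
})

test_that("classical occupancy covers labeling relaxation and wash decay", {
  m <- kinetic_model(1e-3, 20, 0.08)
  expect_equal(classical_occupancy(m, t_label = Inf, t_acq = 0),
               steady_state_occupancy(m))
  expect_equal(classical_occupancy(m, 0, 100), 0)
  # 0.2 * (1 - e^-6) * e^-2.4
  expect_equal(classical_occupancy(m, 60, 30),
               0.2 * (1 - exp(-6)) * exp(-2.4))
  expect_error(classical_occupancy(m, -1, 0), class = "dybe_argument_error")
  # monotone in t_label, decaying in t_acq
  tl <- classical_occupancy(m, c(1, 10, 100, 1000), 0)
  expect_true(all(diff(tl) > 0))
  ta <- classical_occupancy(m, 1000, c(0, 10, 100))
  expect_true(all(diff(ta) < 0))
})

test_that("expected event rate is the occupancy-weighted imager on-rate", {
  expect_equal(expected_event_rate(kinetic_model(1e-3, 20, 0, 6e-3, 1, 2)),
               6e-3)
  expect_equal(expected_event_rate(kinetic_model(1e-3, 20, 0.08, 6e-3, 0, 2)),
               0)
  expect_equal(expected_event_rate(kinetic_model(1e-3, 20, 0.08, 6e-3, 1, 2)),
               0.0012)
})

test_that("site traces satisfy the structural interval invariants", {
  models <- list(
    kinetic_model(1e-3, 20, 0.08),
    kinetic_model(1e-2, 10, 0.5, 6e-3, 5, 2),
    kinetic_model(1e-4, 50, 0.01, 1e-2, 1, 0.5))
  for (i in seq_along(models)) {
    tr <- simulate_site_trace(models[[i]], duration = 2000, seed = 100 + i)
    bi <- tr$binder_intervals
    br <- tr$bright_intervals
    expect_true(all(bi$t_end > bi$t_start))
    expect_true(all(bi$t_start >= 0) && all(bi$t_end <= tr$total_duration))
    if (nrow(bi) > 1) {
      expect_true(all(bi$t_start[-1] >= bi$t_end[-nrow(bi)]))
    }
    if (nrow(br) > 0) {
      # every bright interval inside its owning binder interval
      expect_true(all(br$t_start >= bi$t_start[br$binder] - 1e-12))
      expect_true(all(br$t_end <= bi$t_end[br$binder] + 1e-12))
    }
  }
})

test_that("DyBE trace with zero binder on-rate is empty", {
  tr <- simulate_site_trace(kinetic_model(0, 0, 0.1), duration = 100,
                            seed = 1)
  expect_equal(nrow(tr$binder_intervals), 0)
  expect_equal(nrow(tr$bright_intervals), 0)
})

test_that("time-averaged bound fraction matches the analytic occupancy", {
  # k_on*c = k_off = 0.01 /s over 1e5 s; SE of the time average of a
  # two-state Markov occupancy is sqrt(2 f (1-f) / ((a+b) T))
  m <- kinetic_model(1e-3, 10, 0.01, 0, 0, 1)
  tr <- simulate_site_trace(m, duration = 1e5, seed = 42)
  se <- sqrt(2 * 0.5 * 0.5 / (0.02 * 1e5))
  expect_lt(abs(bound_time_fraction(tr) - 0.5), 3 * se)
})

test_that("bright dwell times follow the imager off-rate for stable binders", {
  # k_off_binder << k_off_imager: blinks are almost never truncated
  m <- kinetic_model(1e-2, 100, 1e-5, 0.06, 10, 2)
  tr <- simulate_site_trace(m, duration = 2e4, seed = 9)
  dw <- tr$bright_intervals$t_end - tr$bright_intervals$t_start
  expect_gt(length(dw), 1000)
  se <- (1 / 2) / sqrt(length(dw))
  expect_lt(abs(mean(dw) - 1 / 2), 4 * se)
})

test_that("bright event counts match the fast-averaging rate prediction", {
  # fast exchange: k_off_imager >> k_off_binder and sparse imager events
  m <- kinetic_model(1e-3, 10, 0.01, 1e-3, 2, 1)
  tr <- simulate_site_trace(m, duration = 2e5, seed = 5)
  n_ev <- nrow(tr$bright_intervals)
  lambda <- expected_event_rate(m) * 2e5
  expect_lt(abs(n_ev - lambda), 4 * sqrt(lambda))
})

test_that("detection summaries respect their invariants and determinism", {
  m <- kinetic_model()
  acq <- acquisition_settings(n_frames = 2000)
  d <- detection_probability(m, acq, mode = "both", n_sites = 500, seed = 11)
  expect_equal(nrow(d), 2)
  expect_true(all(d$n_detected <= d$n_sites))
  expect_equal(d$detection_probability, d$n_detected / d$n_sites)
  expect_true(all(d$ci_lo <= d$detection_probability &
                    d$detection_probability <= d$ci_hi))
  d2 <- detection_probability(m, acq, mode = "both", n_sites = 500, seed = 11)
  expect_identical(d$n_detected, d2$n_detected)
  # no imager, no detection
  m0 <- kinetic_model(c_imager = 0)
  d0 <- detection_probability(m0, acq, mode = "dybe", n_sites = 200, seed = 1)
  expect_equal(d0$n_detected, 0L)
})

test_that("DyBE detection dominates classical detection site-wise", {
  acq <- acquisition_settings(n_frames = 5000)
  for (koff in c(0.02, 0.2, 1)) {
    m <- kinetic_model(1e-3, 20, koff)
    d <- detection_probability(m, acq, mode = "both", t_label = 3600,
                               n_sites = 2000, seed = 77)
    expect_gte(d$n_detected[d$mode == "dybe"],
               d$n_detected[d$mode == "classical"])
  }
})

test_that("strong binders make DyBE and classical detection agree", {
  # k_off_binder -> 0 with saturating labeling: the modes coincide
  acq <- acquisition_settings(n_frames = 2000)
  m <- kinetic_model(1e-3, 20, 1e-6)
  d <- detection_probability(m, acq, mode = "both", t_label = 1e6,
                             n_sites = 4000, seed = 3)
  p <- d$detection_probability
  expect_lt(abs(p[1] - p[2]),
            3 * sqrt(2 * mean(p) * (1 - mean(p) + 1e-9) / 4000) + 1e-9)
})
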