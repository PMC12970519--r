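test_that("mixture NND histograms match CSR for pure labeled monomers", {
  f <- test_field(20000, 20000)
  bins <- seq(0, 200, 5)
  mix <- species_mix(c(mono_A = 0.5, mono_B = 0.5), density = 50)
  h <- simulate_mixture_nnd(mix, 1, 1, measurement_sd = 0, field = f,
                            n_replicates = 2, seed = 1, bin_edges = bins)
  # each channel holds ~ 25 complexes/um^2 of independent CSR points
  rho <- 25 / 1e6
  for (pair in c("AA", "BB", "AB")) {
    d <- h$density[h$pair == pair]
    emp_cdf <- cumsum(d * 5)
    theo_cdf <- csr_nnd_cdf(rho, bins[-1])
    expect_lt(max(abs(emp_cdf - theo_cdf)), 0.03)
  }
})

test_that("pure homodimers concentrate first-NND mass at the dimer distance", {
  f <- test_field(20000, 20000)
  bins <- seq(0, 200, 5)
  mix <- species_mix(c(homo_AA = 1), dimer_distance = 17, density = 10)
  h <- simulate_mixture_nnd(mix, 1, 1, measurement_sd = 1e-9, field = f,
                            n_replicates = 1, seed = 2, bin_edges = bins)
  dAA <- h$density[h$pair == "AA"]
  expect_equal(which.max(dAA), 4)  # [15, 20) bin holds the 17 nm pairs
  expect_gt(dAA[4] * 5, 0.95)
})

test_that("heterodimer content drives short-distance cross-channel mass", {
  f <- test_field(20000, 20000)
  bins <- seq(0, 200, 5)
  mass <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(fh) {
    fr <- c(mono = 1 - fh, hetero = fh)
    h <- simulate_mixture_nnd(species_mix(fr, density = 20), 1, 1,
                              measurement_sd = 5, field = f,
                              n_replicates = 1, seed = 3, bin_edges = bins)
    sum(h$density[h$pair == "AB" & h$bin_lo < 40] * 5)
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("fitted fraction vectors live on the simplex", {
  f <- test_field(15000, 15000)
  pos <- gen_mixture_positions(
    species_mix(c(mono = 0.6, homo = 0.2, hetero = 0.2), density = 10),
    c(A = 0.7, B = 0.7), 10, f, seed = 4)
  fit <- fit_species_fractions(pos$A, pos$B, le_A = 0.7, le_B = 0.7,
                               field = f, grid_step = 0.1,
                               refine_step = 0.1, seed = 5)
  expect_equal(sum(fit$species_fractions), 1)
  expect_true(all(fit$species_fractions >= 0))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(sum(tidy(fit)$fraction), 1)
  expect_equal(nrow(glance(fit)), 1)
  expect_error(fit_species_fractions(pos$A, pos$B, character(0), 0.7, 0.7, f),
               class = "dybe_argument_error")
  expect_error(fit_species_fractions(pos$A, pos$B, le_A = 0, le_B = 0.7,
                                     field = f),
               class = "dybe_argument_error")
})

test_that("the fit is deterministic given a seed", {
  f <- test_field(15000, 15000)
  pos <- gen_mixture_positions(
    species_mix(c(mono = 0.7, hetero = 0.3), density = 10),
    c(A = 0.8, B = 0.8), 10, f, seed = 6)
  f1 <- fit_species_fractions(pos$A, pos$B,
                              candidate_species = c("mono", "hetero"),
                              le_A = 0.8, le_B = 0.8, field = f,
                              grid_step = 0.1, refine_step = 0.05, seed = 7)
  f2 <- fit_species_fractions(pos$A, pos$B,
                              candidate_species = c("mono", "hetero"),
                              le_A = 0.8, le_B = 0.8, field = f,
                              grid_step = 0.1, refine_step = 0.05, seed = 7)
  expect_identical(f1$species_fractions, f2$species_fractions)
  expect_identical(f1$grid, f2$grid)
})

test_that("pure monomers do not hallucinate dimers in the fit", {
  f <- test_field(20000, 20000)
  pos <- gen_mixture_positions(
    species_mix(c(mono_A = 0.5, mono_B = 0.5), density = 15),
    c(A = 0.7, B = 0.7), 10, f, seed = 8)
  fit <- fit_species_fractions(pos$A, pos$B, le_A = 0.7, le_B = 0.7,
                               field = f, seed = 9)
  dimer <- sum(fit$species_fractions[c("homo", "hetero")])
  expect_lte(dimer, 0.05)
})

test_that("an all-heterodimer truth is recovered at ideal labeling", {
  # ~5000 molecules per channel, the scale of a well-expressed receptor
  f <- test_field(15000, 15000)
  pos <- gen_mixture_positions(species_mix(c(hetero = 1), density = 22),
                               c(A = 1, B = 1), 10, f, seed = 10)
  fit <- fit_species_fractions(pos$A, pos$B, le_A = 1, le_B = 1, field = f,
                               seed = 11)
  expect_gte(fit$species_fractions["hetero"], 0.9)
})

test_that("identifiability: distant mixtures score worse than the truth", {
  f <- test_field(15000, 15000)
  truth <- c(mono = 0.5, homo = 0.3, hetero = 0.2)
  pos <- gen_mixture_positions(species_mix(truth, density = 15),
                               c(A = 0.7, B = 0.7), 10, f, seed = 12)
  fit <- fit_species_fractions(pos$A, pos$B, le_A = 0.7, le_B = 0.7,
                               field = f, grid_step = 0.05,
                               refine_step = 0.05, seed = 13)
  g <- fit$grid
  dist_inf <- pmax(abs(g$mono - truth["mono"]), abs(g$homo - truth["homo"]),
                   abs(g$hetero - truth["hetero"]))
  best_near <- min(g$objective[dist_inf < 0.15])
  expect_true(all(g$objective[dist_inf >= 0.15] > best_near))
})

test_that("lower labeling efficiency degrades recovery accuracy", {
  f <- test_field(15000, 15000)
  truth <- c(mono = 0.5, homo = 0.3, hetero = 0.2)
  mae <- function(le, seeds) {
    mean(vapply(seeds, function(s) {
      pos <- gen_mixture_positions(species_mix(truth, density = 15),
                                   c(A = le, B = le), 10, f, seed = s)
      fit <- fit_species_fractions(pos$A, pos$B, le_A = le, le_B = le,
                                   field = f, grid_step = 0.05,
                                   refine_step = 0.05, seed = s + 1000)
      mean(abs(fit$species_fractions - truth))
    }, numeric(1)))
  }
  seeds <- c(21, 22, 23)
  expect_gte(mae(0.3, seeds) + 1e-9, mae(0.7, seeds))
})

test_that("apparent dimer fraction separates CSR from paired patterns", {
  f <- test_field(20000, 20000)
  withr::with_seed(30, pts <- csr_points(4000, f))
  expect_lt(apparent_dimer_fraction(pts, 20, f), 0.02)
  # perfect pairs at 10 nm
  withr::with_seed(31, {
    seeds_xy <- csr_points(2000, f)
    partners <- tibble::tibble(x = (seeds_xy$x + 10) %% f$width,
                               y = seeds_xy$y)
  })
  pairs <- dplyr::bind_rows(seeds_xy, partners)
  expect_gt(apparent_dimer_fraction(pairs, 20, f), 0.9)
  expect_error(apparent_dimer_fraction(pairs[1, ], 20, f),
               class = "dybe_argument_error")
})
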