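test_that("population_spec validates frequencies, spreads and correlations", {
  expect_error(population_spec("a", 0, 1:3, 1), "frequency")
  expect_error(population_spec("a", 1.2, 1:3, 1), "frequency")
  expect_error(population_spec("a", 0.5, 1:3, c(1, -1, 1)), "spread")
  bad_cor <- matrix(c(1, 2, 2, 1), 2, 2)  # not PSD
  expect_error(population_spec("a", 0.5, 1:2, 1, bad_cor),
               "positive semi-definite")
  asym <- matrix(c(1, 0.2, 0.6, 1), 2, 2)
  expect_error(population_spec("a", 0.5, 1:2, 1, asym), "symmetric")
})

test_that("single-population mixture matches its centroid", {
  spec <- population_spec("solo", 1, centroid = c(2, -1, 0.5), spread = 0.3)
  ds <- generate_mixture(list(spec), 4000, seed = 11)
  expect_true(all(ds$labels == "solo"))
  err <- abs(colMeans(ds$matrix) - c(2, -1, 0.5))
  expect_true(all(err < 3 * 0.3 / sqrt(4000)))
})

test_that("default panel frequencies, rare class and degenerate separation", {
  panel <- default_cytometry_panel()
  freqs <- vapply(panel, `[[`, numeric(1), "frequency")
  expect_equal(sum(freqs), 1, tolerance = 1e-9)
  expect_equal(freqs[length(freqs)], 0.005)
  expect_equal(panel[[length(panel)]]$name, "rare")
  # signatures pairwise distinct
  cents <- t(vapply(panel, `[[`, numeric(11), "centroid"))
  expect_equal(nrow(unique(cents)), length(panel))

  two <- default_cytometry_panel(n_populations = 2, rare_fraction = 0.005)
  expect_equal(vapply(two, `[[`, numeric(1), "frequency"), c(0.995, 0.005))

  flat <- default_cytometry_panel(separation = 0)
  cents0 <- t(vapply(flat, `[[`, numeric(11), "centroid"))
  expect_true(all(cents0 == 0))

  expect_error(default_cytometry_panel(n_populations = 10,
                                       rare_fraction = 0.2),
               "rare_fraction")
})

test_that("multinomial draws put the rare class within Poisson bounds", {
  panel <- default_cytometry_panel(n_populations = 10, n_channels = 15)
  ds <- generate_mixture(panel, 20000, seed = 21)
  expect_equal(ncol(ds$matrix), 15)
  rare_n <- sum(ds$labels == "rare")
  # expected 100; +/- 4 sd of Poisson(100)
  expect_gt(rare_n, 100 - 4 * 10)
  expect_lt(rare_n, 100 + 4 * 10)
})

test_that("generation is bit-deterministic in the seed", {
  panel <- default_cytometry_panel(n_populations = 5, n_channels = 6)
  d1 <- generate_mixture(panel, 1000, seed = 33)
  d2 <- generate_mixture(panel, 1000, seed = 33)
  expect_identical(d1$matrix, d2$matrix)
  expect_identical(d1$labels, d2$labels)
  d3 <- generate_mixture(panel, 1000, seed = 34)
  expect_false(identical(d1$matrix, d3$matrix))
})

test_that("correlated populations honour the requested covariance", {
  cor_m <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  spec <- population_spec("c", 1, c(0, 0), c(1, 2), correlation = cor_m)
  ds <- generate_mixture(list(spec), 20000, seed = 8)
  emp <- cor(ds$matrix)
  expect_equal(emp[1, 2], 0.8, tolerance = 0.02)
  expect_equal(unname(apply(ds$matrix, 2, sd)), c(1, 2), tolerance = 0.05)
})

test_that("generator moments converge at large n", {
  panel <- default_cytometry_panel(n_populations = 4, n_channels = 6,
                                   separation = 3)
  ds <- generate_mixture(panel, 1e5, seed = 13)
  for (p in panel) {
    rows <- ds$labels == p$name
    # sampling bound scales with the population size (the rare class has
    # only ~500 of the 1e5 events)
    bound <- 4 * max(p$spread) / sqrt(sum(rows))
    expect_lt(max(abs(colMeans(ds$matrix[rows, ]) - p$centroid)), bound)
    expect_lt(max(abs(apply(ds$matrix[rows, ], 2, sd) - p$spread)),
              0.01 + bound)
  }
})

test_that("synthetic KLD traces expose the morphology the detector needs", {
  # noise-free plateau trace: the detector recovers the analytic peak
  tr <- synth_kld_trace("plateau_then_descent", length = 120)
  rc <- c(NA, kldrc(tr[-length(tr)], tr[-1]))
  d <- detect_max_kldrc(rc, min_ee_iterations = 15, patience = 3)
  expect_true(d$fired)
  expect_equal(d$peak_iteration, attr(tr, "peak_iteration"))

  # constant-ratio decay: constant KLDRC, no local maximum fires
  tm <- synth_kld_trace("monotone", length = 100)
  rcm <- c(NA, kldrc(tm[-100], tm[-1]))
  expect_equal(diff(range(rcm[-1])), 0, tolerance = 1e-9)
  expect_false(detect_max_kldrc(rcm, 15, 3)$fired)

  # determinism of the noisy fixture
  t1 <- synth_kld_trace("plateau_then_descent", 120, noise_sd = 5e-4,
                        seed = 3)
  t2 <- synth_kld_trace("plateau_then_descent", 120, noise_sd = 5e-4,
                        seed = 3)
  expect_identical(as.numeric(t1), as.numeric(t2))

  # spiky traces stay positive and deterministic
  sp <- synth_kld_trace("spiky", 90, seed = 2)
  expect_true(all(sp > 0))
  expect_gt(max(abs(sp - attr(sp, "clean"))), 0)
})

test_that("detector robustness on noisy traces: solid at 0.05% jitter, degraded at 1%", {
  hit_rate <- function(noise_sd) {
    hits <- 0L
    for (s in 1:20) {
      tn <- synth_kld_trace("plateau_then_descent", 120, noise_sd = noise_sd,
                            seed = s)
      rc <- c(NA, kldrc(tn[-120], tn[-1]))
      d <- detect_max_kldrc(rc, 15, 3)
      if (d$fired &&
          abs(d$ee_stop_iteration - attr(tn, "peak_iteration")) <= 3)
        hits <- hits + 1L
    }
    hits
  }
  # smooth-trace regime (real descent traces): >= 18/20 within +/- patience
  expect_gte(hit_rate(5e-4), 18L)
  # iid jitter at 1% of the KLD overwhelms a patience-3 running max:
  # the detector fires on plateau noise, documenting why patience/burn-in
  # must grow with trace noise
  expect_lt(hit_rate(0.01), 18L)
})
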