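test_that("auto learning rate follows n/alpha with the classical floor", {
  expect_equal(auto_learning_rate(12, 12), 200)        # floor applies
  expect_equal(auto_learning_rate(1e6, 12), 83333)     # large-n regime
  expect_equal(auto_learning_rate(2400, 4), 600)
  expect_equal(auto_learning_rate(1000, 1), 1000)

  # monotone non-decreasing in n, non-increasing in alpha
  ns <- c(10, 100, 1000, 1e4, 1e5, 1e6)
  expect_true(all(diff(vapply(ns, auto_learning_rate, 1, alpha = 12)) >= 0))
  alphas <- c(1, 2, 4, 12, 30)
  expect_true(all(diff(vapply(alphas, function(a)
    auto_learning_rate(5e4, a), 1)) <= 0))
})

test_that("the alpha*eta > n stability condition is flagged strictly", {
  expect_equal(check_ls_condition(1e6, 12, 200), "OK")
  expect_equal(check_ls_condition(1e6, 12, 256000), "WARN")
  expect_equal(check_ls_condition(2400, 12, 200), "OK")     # equality is OK
  expect_equal(check_ls_condition(2399, 12, 200), "WARN")
})

test_that("KLDRC formula arithmetic and domain errors", {
  expect_equal(kldrc(10, 9), 10)
  expect_equal(kldrc(5, 5), 0)
  expect_equal(kldrc(4, 4.2), -5)
  expect_equal(kldrc(c(10, 5), c(9, 5)), c(10, 0))
  expect_error(kldrc(0, 1), "positive")
  expect_error(kldrc(-2, 1), "positive")
})

test_that("maxKLDRC detector confirms the local maximum after patience", {
  d <- detect_max_kldrc(c(1, 2, 3, 5, 4, 3, 2), min_ee_iterations = 0,
                        patience = 3)
  expect_true(d$fired)
  expect_equal(d$peak_iteration, 4L)
  expect_equal(d$ee_stop_iteration, 5L)
  expect_equal(d$fire_iteration, 7L)

  # monotonically rising: no local maximum, never fires
  expect_false(detect_max_kldrc(1:50, 0, 3)$fired)

  # burn-in shields the early transient
  tr <- c(9, 0.1, 0.2, 0.3, rep(0.4, 12), 1, 2, 6, 3, 2, 1)
  d2 <- detect_max_kldrc(tr, min_ee_iterations = 15, patience = 3)
  expect_true(d2$fired)
  expect_equal(d2$peak_iteration, which.max(tr[-1]) + 1L)

  # not-yet answer on an unfinished trace
  expect_false(detect_max_kldrc(c(1, 2, 3, 5, 4), 0, 3)$fired)

  # NA first entry (iteration 1 has no KLDRC) is skipped
  expect_true(detect_max_kldrc(c(NA, 1, 5, 2, 2, 2), 0, 3)$fired)
})

test_that("termination rule implements the relative-improvement inequality", {
  expect_true(check_termination(2.0000, 1.9999, 5000))
  expect_false(check_termination(2.2, 2.0, 5000))
  expect_true(check_termination(2.0, 2.1, 5000))   # an increase terminates
  expect_false(check_termination(2.0, 1.0, 0))     # X = 0 disables
  # X = 5000 is the 1/5000 = 0.02% relative-improvement boundary
  kld <- 3
  expect_false(check_termination(kld * (1 + 3e-4), kld, 5000))
  expect_true(check_termination(kld * (1 + 1e-4), kld, 5000))
})

test_that("config validation guards the run parameters", {
  expect_error(embedding_config(alpha = 0.5), "alpha")
  expect_error(embedding_config(eta = -5), "eta")
  expect_error(embedding_config(theta = 1.2), "theta")
  expect_error(embedding_config(termination_divisor = -1), "termination")
  expect_error(embedding_config(max_iterations = 5, min_ee_iterations = 10),
               "max_iterations")
  cfg <- embedding_config()
  expect_identical(cfg$ee_stop, "auto")
  expect_identical(cfg$eta, "auto")
})

test_that("a full run is seed-deterministic and self-consistent", {
  ds <- generate_mixture(default_cytometry_panel(n_populations = 5,
                                                 n_channels = 6),
                         1500, seed = 4)
  cfg <- embedding_config(seed = 9, max_iterations = 2000)
  r1 <- suppressWarnings(run_optsne(ds, cfg))
  r2 <- suppressWarnings(run_optsne(ds, cfg))
  expect_identical(r1$coords, r2$coords)
  expect_identical(r1$kld_trace, r2$kld_trace)
  expect_identical(r1$kldrc_trace, r2$kldrc_trace)

  # structural invariants of the result
  expect_lte(r1$ee_stop_iteration, r1$total_iterations)
  expect_equal(r1$endpoint_kld, r1$kld_trace[r1$total_iterations])
  expect_equal(length(r1$kld_trace), r1$total_iterations)
  expect_equal(unname(colMeans(r1$coords)), c(0, 0), tolerance = 1e-12)
  # KLD drops discontinuously at EE removal
  i <- r1$ee_stop_iteration
  expect_gt(r1$kld_trace[i] - r1$kld_trace[i + 1], 0)
  expect_identical(r1$phase_trace[i], "EE")
  expect_identical(r1$phase_trace[i + 1], "POST_EE")
  # eta resolved to the floored n/alpha rule
  expect_equal(r1$eta, auto_learning_rate(1500, 12))
})

test_that("fixed-parameter configuration reproduces the standard t-SNE schedule", {
  ds <- generate_mixture(default_cytometry_panel(n_populations = 4,
                                                 n_channels = 5),
                         800, seed = 2)
  cfg <- embedding_config(eta = 200, ee_stop = 250,
                          termination_divisor = 0, max_iterations = 400,
                          seed = 1)
  r <- suppressWarnings(run_optsne(ds, cfg))
  expect_equal(r$ee_stop_iteration, 250L)
  expect_equal(r$total_iterations, 400L)       # no auto termination
  expect_equal(r$eta, 200)
  expect_true(all(r$phase_trace[1:250] == "EE"))
  expect_true(all(r$phase_trace[251:400] == "POST_EE"))
})

test_that("unstable learning rates trigger the advisory warning", {
  ds <- generate_mixture(default_cytometry_panel(n_populations = 4,
                                                 n_channels = 5),
                         500, seed = 3)
  expect_warning(
    run_optsne(ds, embedding_config(eta = 500, ee_stop = 30,
                                    max_iterations = 40, seed = 1,
                                    termination_divisor = 0)),
    "alpha \\* eta")
})

test_that("precomputed affinities are validated and reused", {
  ds <- generate_mixture(default_cytometry_panel(n_populations = 4,
                                                 n_channels = 5),
                         600, seed = 6)
  aff <- symmetrize_affinities(build_conditional_affinities(ds, 30))
  cfg <- embedding_config(seed = 2, max_iterations = 500)
  r1 <- suppressWarnings(run_optsne(ds, cfg, affinities = aff))
  r2 <- suppressWarnings(run_optsne(ds, cfg))
  expect_identical(r1$coords, r2$coords)

  expect_error(suppressWarnings(run_optsne(ds, cfg,
                                           affinities = exaggerate(aff, 2))),
               "unexaggerated")
  other <- generate_mixture(default_cytometry_panel(n_populations = 4,
                                                    n_channels = 5),
                            500, seed = 1)
  expect_error(suppressWarnings(run_optsne(other, cfg, affinities = aff)),
               "different number of points")
})
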