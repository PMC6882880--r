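make_model <- function(n, d = 4, perplexity = 8, seed = 1) {
  x <- withr::with_seed(seed, matrix(rnorm(n * d), n, d))
  list(x = x,
       model = symmetrize_affinities(build_conditional_affinities(
         x, perplexity, k_neighbors = n - 1L)))
}

test_that("two points: q = 1/2 and KLD matches the closed form", {
  # with n = 2 the Cauchy similarities normalise to exactly 1/2 each way
  p <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(0.3, 0.7),
                            dims = c(2, 2))
  model <- structure(list(P = methods::as(p, "CsparseMatrix"),
                          perplexity = 1, bandwidths = c(1, 1),
                          k_neighbors = 1L, n = 2L, exaggeration = 1),
                     class = "optsne_affinities")
  y <- rbind(c(0, 0), c(3, 4))
  out <- compute_q_and_kld(model, y, theta = 0)
  expect_equal(out$Z, 2 / (1 + 25), tolerance = 1e-12)
  expect_equal(out$kld, 0.3 * log(0.3 / 0.5) + 0.7 * log(0.7 / 0.5),
               tolerance = 1e-12)
})

test_that("KLD is zero when Q equals P on the support", {
  # four points at the corners of a square: all pairwise structures equal
  # by symmetry except diagonals; build P from Q itself
  y <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  oracle <- dense_gradient_oracle(matrix(1 / 12, 4, 4) - diag(4) / 12, y)
  p <- Matrix::Matrix(oracle$q, sparse = TRUE)
  model <- structure(list(P = methods::as(p, "CsparseMatrix"),
                          perplexity = 1, bandwidths = rep(1, 4),
                          k_neighbors = 3L, n = 4L, exaggeration = 1),
                     class = "optsne_affinities")
  out <- compute_q_and_kld(model, y, theta = 0)
  expect_equal(out$kld, 0, tolerance = 1e-12)
})

test_that("theta = 0 gradient and KLD match the dense brute-force oracle", {
  for (n in c(60, 150)) {
    mk <- make_model(n, seed = n)
    y <- withr::with_seed(n + 1, matrix(rnorm(n * 2), n, 2))
    oracle <- dense_gradient_oracle(as.matrix(mk$model$P), y)
    grad <- tsne_gradient(mk$model, y, theta = 0)
    out <- compute_q_and_kld(mk$model, y, theta = 0)
    expect_lt(max(abs(grad - oracle$grad)), 1e-10)
    expect_lt(abs(out$kld - oracle$kld), 1e-10)
    expect_equal(out$Z, oracle$Z, tolerance = 1e-12)
  }
})

test_that("exaggerated P scales the attractive term and inflates the KLD", {
  mk <- make_model(80)
  y <- withr::with_seed(99, matrix(rnorm(160), 80, 2))
  ex <- exaggerate(mk$model, 12)
  oracle <- dense_gradient_oracle(as.matrix(mk$model$P) * 12, y)
  expect_lt(max(abs(tsne_gradient(ex, y, 0) - oracle$grad)), 1e-10)
  kld_plain <- compute_q_and_kld(mk$model, y, 0)$kld
  kld_ex <- compute_q_and_kld(ex, y, 0)$kld
  expect_lt(abs(kld_ex - oracle$kld), 1e-10)
  expect_gt(kld_ex, kld_plain)
})

test_that("Barnes-Hut KLD stays within 1% of exact and error grows with theta", {
  mk <- make_model(100, seed = 42)
  y <- withr::with_seed(5, matrix(rnorm(200, sd = 5), 100, 2))
  exact <- compute_q_and_kld(mk$model, y, theta = 0)
  bh <- compute_q_and_kld(mk$model, y, theta = 0.5)
  expect_lt(abs(bh$kld - exact$kld) / exact$kld, 0.01)

  g_exact <- tsne_gradient(mk$model, y, 0)
  err <- function(theta) max(abs(tsne_gradient(mk$model, y, theta) - g_exact))
  expect_gte(err(0.8), err(0.2))
})

test_that("gradient mirror-equivariance and coincident-point finiteness", {
  mk <- make_model(50, seed = 8)
  y <- withr::with_seed(12, matrix(rnorm(100), 50, 2))
  g <- tsne_gradient(mk$model, y, 0)
  y_flip <- y
  y_flip[, 1] <- -y_flip[, 1]
  g_flip <- tsne_gradient(mk$model, y_flip, 0)
  expect_equal(g_flip[, 1], -g[, 1], tolerance = 1e-14)
  expect_equal(g_flip[, 2], g[, 2], tolerance = 1e-14)

  y_dup <- y
  y_dup[2, ] <- y_dup[1, ]  # coincident pair stays finite via the floor
  expect_true(all(is.finite(tsne_gradient(mk$model, y_dup, 0))))
  expect_true(all(is.finite(tsne_gradient(mk$model, y_dup, 0.5))))
})

test_that("jacobs_step follows the delta-bar-delta rule", {
  # fixed point at zero gradient / zero velocity
  st <- optimization_state(matrix(c(1, 2, 3, 4), 2, 2))
  out <- jacobs_step(st, matrix(0, 2, 2), gradient_settings(eta = 1))
  expect_equal(out$coords, st$coords)
  expect_equal(out$iteration, 1L)

  # 1-D quadratic toy, two hand-worked iterations:
  # f(y) = y^2, grad = 2y, start y = 1, eta = 0.1, momentum 0.5,
  # gain +0.2 / x0.8, floor 0.01
  st <- optimization_state(matrix(c(1, 0), 1, 2))
  s <- gradient_settings(eta = 0.1, momentum_early = 0.5)
  st <- jacobs_step(st, matrix(c(2 * st$coords[1, 1], 0), 1, 2), s)
  # gain 1.2 (sign(grad) != sign(0)), update = -0.1 * 1.2 * 2 = -0.24
  expect_equal(st$coords[1, 1], 0.76, tolerance = 1e-12)
  st <- jacobs_step(st, matrix(c(2 * st$coords[1, 1], 0), 1, 2), s)
  # gain 1.4, update = 0.5 * (-0.24) - 0.1 * 1.4 * 1.52 = -0.3328
  expect_equal(st$coords[1, 1], 0.4272, tolerance = 1e-12)

  # constant-sign gradient: gains grow monotonically while velocity
  # opposes the gradient
  st <- optimization_state(matrix(c(5, 0), 1, 2))
  gains <- numeric(6)
  for (k in 1:6) {
    st <- jacobs_step(st, matrix(c(1, 0), 1, 2), gradient_settings(eta = 0.01))
    gains[k] <- st$gains[1, 1]
  }
  expect_true(all(diff(gains) > 0))
})

test_that("plain descent decreases the KLD monotonically on a toy", {
  mk <- make_model(200, perplexity = 10, seed = 21)
  y <- withr::with_seed(3, matrix(rnorm(400, sd = 1e-2), 200, 2))
  st <- optimization_state(y)
  s <- gradient_settings(eta = 1, momentum_early = 0, momentum_late = 0)
  klds <- numeric(20)
  for (k in 1:20) {
    klds[k] <- compute_q_and_kld(mk$model, st$coords, 0)$kld
    st <- jacobs_step(st, tsne_gradient(mk$model, st$coords, 0), s)
  }
  expect_true(all(diff(klds) <= 0))
})
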