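# Independent dense brute-force oracles: all-pairs computations written
# directly from the model formulas, against which the sparse/Barnes-Hut
# engine is checked. They share only the package's documented numerical
# floors (squared distances at 1e-12, probabilities at 1e-12 in logs).

# Per-point Gaussian conditionals over all n-1 neighbours, bandwidths by
# bisection on the precision so the entropy matches log(perplexity) nats.
dense_affinity_oracle <- function(x, perplexity, tol = 1e-5,
                                  max_iter = 200L) {
  x <- as.matrix(x)
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  p_cond <- matrix(0, n, n)
  beta <- numeric(n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    b <- 1
    b_lo <- -Inf
    b_hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-b * di)
      s <- sum(w)
      h <- log(s) + b * sum(di * w) / s
      if (!is.finite(h) || abs(h - log_u) < tol) break
      if (h > log_u) {
        b_lo <- b
        b <- if (is.finite(b_hi)) (b + b_hi) / 2 else 2 * b
      } else {
        b_hi <- b
        b <- if (is.finite(b_lo)) (b + b_lo) / 2 else b / 2
      }
    }
    p_cond[i, -i] <- w / s
    beta[i] <- b
  }
  list(p_cond = p_cond, beta = beta, sigma = sqrt(1 / (2 * beta)),
       p_joint = (p_cond + t(p_cond)) / (2 * n))
}

# Exact embedding-space quantities from dense double loops: Cauchy kernel,
# normalisation Z over all ordered pairs, KLD over the support of P, and
# the full gradient 4 * sum_j (p_ij - q_ij) qnum_ij (y_i - y_j).
dense_gradient_oracle <- function(p_joint, y) {
  y <- as.matrix(y)
  n <- nrow(y)
  d2 <- pmax(as.matrix(dist(y))^2, 1e-12)
  qnum <- 1 / (1 + d2)
  diag(qnum) <- 0
  z <- sum(qnum)
  q <- qnum / z
  grad <- matrix(0, n, 2)
  w <- (p_joint - q) * qnum
  for (i in seq_len(n)) {
    grad[i, ] <- 4 * colSums(w[i, ] * sweep(-y, 2, -y[i, ]))
  }
  on_support <- p_joint > 0
  kld <- sum(p_joint[on_support] *
               (log(pmax(p_joint[on_support], 1e-12)) -
                  log(pmax(q[on_support], 1e-12))))
  list(grad = grad, kld = kld, Z = z, q = q)
}

# Shannon perplexity (2^H, H in bits) of each row of a conditional
# probability matrix, the quantity the calibration must hit.
row_perplexity <- function(prob) {
  apply(prob, 1, function(p) {
    p <- p[p > 0]
    2^(-sum(p * log2(p)))
  })
}
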