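#' Configuration of an opt-SNE run
#'
#' Defaults follow the opt-SNE workflow for cytometry-scale data: early
#' exaggeration factor `alpha = 12`, learning rate resolved automatically
#' to `floor(n / alpha)` (never below the classical 200), early
#' exaggeration removed at the confirmed local maximum of the relative
#' rate of KLD change (maxKLDRC), and the run finalized when an iteration
#' improves the KLD by less than `1/termination_divisor` of its value
#' (the default divisor 5000 corresponds to a 1/5000 = 0.02% relative
#' improvement).
#'
#' @param perplexity target perplexity (soft neighbour count), default 30.
#' @param alpha early exaggeration factor, `>= 1`, default 12.
#' @param eta `"auto"` (resolved to [auto_learning_rate()] at run start) or
#'   a fixed positive step size.
#' @param theta Barnes-Hut opening parameter, default 0.5.
#' @param ee_stop `"auto"` (maxKLDRC detection) or a fixed iteration count.
#' @param termination_divisor the `X` in the stopping rule
#'   `(KLD_[N-1] - KLD_N) < KLD_N / X`; `0` disables automatic termination.
#' @param max_iterations safety cap on total iterations, default 5000.
#' @param min_ee_iterations burn-in before maxKLDRC detection may fire,
#'   default 15 (skips the first-iterations KLD transient).
#' @param min_post_ee_iterations burn-in after exaggeration removal before
#'   the termination rule is evaluated, default 15: instantaneous EE
#'   removal leaves a few iterations of momentum/gain carry-over during
#'   which the KLD can transiently rise, which the signed termination rule
#'   must not mistake for convergence.
#' @param kldrc_patience iterations the KLDRC running maximum must stand
#'   unbeaten before it is confirmed as the peak, default 3.
#' @param termination_consecutive number of consecutive iterations that
#'   must satisfy the termination inequality, default 1.
#' @param k_neighbors affinity neighbour-list size; `NULL` for the
#'   `floor(3 * perplexity)` default.
#' @param momentum_early,momentum_late momentum during/after early
#'   exaggeration (0.5 / 0.8).
#' @param seed integer seed for the random initialization.
#' @return an `optsne_config` list.
#' @export
embedding_config <- function(perplexity = 30, alpha = 12, eta = "auto",
                             theta = 0.5, ee_stop = "auto",
                             termination_divisor = 5000,
                             max_iterations = 5000L,
                             min_ee_iterations = 15L,
                             min_post_ee_iterations = 15L,
                             kldrc_patience = 3L,
                             termination_consecutive = 1L,
                             k_neighbors = NULL,
                             momentum_early = 0.5, momentum_late = 0.8,
                             seed = 42L) {
  if (!is_scalar_number(perplexity) || perplexity <= 0)
    stop("`perplexity` must be positive")
  if (!is_scalar_number(alpha) || alpha < 1) stop("`alpha` must be >= 1")
  if (!identical(eta, "auto") && (!is_scalar_number(eta) || eta <= 0))
    stop('`eta` must be "auto" or a positive number')
  if (!is_scalar_number(theta) || theta < 0 || theta >= 1)
    stop("`theta` must be in [0, 1)")
  if (!identical(ee_stop, "auto") &&
      (!is_scalar_number(ee_stop) || ee_stop < 1))
    stop('`ee_stop` must be "auto" or a positive iteration count')
  if (!is_scalar_number(termination_divisor) || termination_divisor < 0)
    stop("`termination_divisor` must be >= 0 (0 disables termination)")
  max_iterations <- as.integer(max_iterations)
  min_ee_iterations <- as.integer(min_ee_iterations)
  if (max_iterations < min_ee_iterations)
    stop("`max_iterations` must be >= `min_ee_iterations`")

  structure(
    list(perplexity = perplexity, alpha = alpha, eta = eta, theta = theta,
         ee_stop = if (identical(ee_stop, "auto")) "auto"
                   else as.integer(ee_stop),
         termination_divisor = termination_divisor,
         max_iterations = max_iterations,
         min_ee_iterations = min_ee_iterations,
         min_post_ee_iterations = as.integer(min_post_ee_iterations),
         kldrc_patience = as.integer(kldrc_patience),
         termination_consecutive = as.integer(termination_consecutive),
         k_neighbors = k_neighbors,
         momentum_early = momentum_early, momentum_late = momentum_late,
         seed = as.integer(seed)),
    class = "optsne_config")
}

#' Dataset-scaled initial learning rate
#'
#' The opt-SNE rule `eta = n / alpha`, floored at the classical default of
#' 200 so small datasets never descend slower than standard t-SNE.
#'
#' @param n number of datapoints.
#' @param alpha early exaggeration factor.
#' @return `max(200, floor(n / alpha))`.
#' @export
auto_learning_rate <- function(n, alpha) {
  if (!is_scalar_number(n) || n < 1) stop("`n` must be >= 1")
  if (!is_scalar_number(alpha) || alpha < 1) stop("`alpha` must be >= 1")
  max(200, floor(n / alpha))
}

#' Linderman-Steinerberger stability diagnostic
#'
#' For a fixed learning rate, t-SNE is not guaranteed to converge when the
#' product of the exaggeration factor and the step size exceeds the number
#' of datapoints. With an adaptive step the condition is advisory, so the
#' run proceeds; `"WARN"` flags the `alpha * eta > n` regime in which
#' irregular KLD spikes have been observed.
#'
#' @param n number of datapoints.
#' @param alpha early exaggeration factor.
#' @param eta initial learning-rate step size.
#' @return `"OK"` or `"WARN"` (strict inequality: `alpha * eta == n` is OK).
#' @export
check_ls_condition <- function(n, alpha, eta) {
  stopifnot(n > 0, alpha > 0, eta > 0)
  if (alpha * eta > n) "WARN" else "OK"
}

#' Relative rate of KLD change (percent)
#'
#' `KLDRC_N = 100 * (KLD_[N-1] - KLD_N) / KLD_[N-1]`. Negative when the
#' KLD rose. Vectorized over its arguments.
#'
#' @param kld_prev KLD at the previous iteration, must be `> 0`.
#' @param kld_curr KLD at the current iteration.
#' @return percent change(s).
#' @export
kldrc <- function(kld_prev, kld_curr) {
  if (any(!is.finite(kld_prev)) || any(kld_prev <= 0))
    stop("`kld_prev` must be positive and finite")
  100 * (kld_prev - kld_curr) / kld_prev
}

#' Confirmed-local-maximum detector for KLDRC
#'
#' Maintains a running maximum of the KLDRC trace past a burn-in. The peak
#' is confirmed (the detector "fires") at the first iteration lying at
#' least `patience` iterations after the running maximum was last set or
#' tied, with every intervening value strictly below it. The iteration
#' after the peak is reported as the early exaggeration stop.
#'
#' @param kldrc_trace numeric KLDRC values, indexed from iteration 1;
#'   non-finite entries (e.g. the undefined first iteration) are skipped.
#' @param min_ee_iterations burn-in: iterations `<= min_ee_iterations` are
#'   ignored.
#' @param patience confirmation window length.
#' @param tie_tol values within this relative tolerance of the running
#'   maximum count as ties and refresh it (default `1e-9`), so a
#'   constant-KLDRC trace never fires on last-digit rounding jitter.
#' @return list with `fired` (logical), `peak_iteration`,
#'   `ee_stop_iteration` (`peak_iteration + 1`), and `fire_iteration` (the
#'   index at which confirmation happened); the last three are `NA` until
#'   the detector fires.
#' @export
detect_max_kldrc <- function(kldrc_trace, min_ee_iterations = 15L,
                             patience = 3L, tie_tol = 1e-9) {
  m_val <- -Inf
  m_idx <- NA_integer_
  for (t in seq_along(kldrc_trace)) {
    if (t <= min_ee_iterations) next
    v <- kldrc_trace[t]
    if (!is.finite(v)) next
    if (v >= m_val - tie_tol * max(1, abs(m_val))) {
      m_val <- max(m_val, v)
      m_idx <- t
    } else if (!is.na(m_idx) && (t - m_idx) >= patience) {
      return(list(fired = TRUE,
                  peak_iteration = m_idx,
                  ee_stop_iteration = m_idx + 1L,
                  fire_iteration = t))
    }
  }
  list(fired = FALSE, peak_iteration = NA_integer_,
       ee_stop_iteration = NA_integer_, fire_iteration = NA_integer_)
}

#' Relative-improvement termination rule
#'
#' True when `(kld_prev - kld_curr) < kld_curr / X`, i.e. the iteration
#' improved the KLD by less than a `1/X` fraction of its current value
#' (1/5000 = 0.02% for the default `X = 5000`). A KLD increase also satisfies the
#' inequality and terminates: past convergence, oscillation should end the
#' run. `X = 0` disables the rule.
#'
#' @param kld_prev,kld_curr consecutive (post-exaggeration) KLD values.
#' @param X termination divisor.
#' @return logical.
#' @export
check_termination <- function(kld_prev, kld_curr, X = 5000) {
  if (X <= 0) return(FALSE)
  (kld_prev - kld_curr) < kld_curr / X
}

#' Run an opt-SNE embedding
#'
#' Orchestrates the full run: builds (or reuses) the perplexity-calibrated
#' affinities, applies early exaggeration, initializes the 2-D coordinates
#' from the seed (isotropic Gaussian, sd 1e-4), and iterates Jacobs-gain
#' gradient descent while recording the KLD and KLDRC at every iteration.
#' In automatic mode the exaggeration is removed instantaneously (P divided
#' by `alpha`) when [detect_max_kldrc()] confirms the KLDRC peak; the KLD
#' then drops discontinuously and the termination rule
#' [check_termination()] is evaluated only on post-exaggeration pairs of
#' iterations, never across the phase boundary. Coordinates are re-centered
#' after every iteration.
#'
#' @param data numeric event x channel matrix or a `labeled_dataset`.
#' @param config an [embedding_config()].
#' @param affinities optional precomputed, unexaggerated
#'   [symmetrize_affinities()] model for `data` (useful when embedding the
#'   same data under several seeds or configurations).
#' @param trace_file optional path; when given, a tab-separated per-
#'   iteration log (iteration, phase, kld, kldrc, gain_mean, gain_max) is
#'   streamed to it.
#' @param verbose print progress every 50 iterations.
#' @return an `optsne_result`: `coords`, `kld_trace`, `kldrc_trace`,
#'   `phase_trace`, `ee_stop_iteration` (iteration after which exaggeration
#'   was removed), `kldrc_peak_iteration`, `total_iterations`,
#'   `endpoint_kld` (last unexaggerated KLD), resolved `eta`, the
#'   Linderman-Steinerberger flag, the config echo, the seed, and a
#'   fingerprint of the input data.
#' @export
run_optsne <- function(data, config = embedding_config(), affinities = NULL,
                       trace_file = NULL, verbose = FALSE) {
  if (!inherits(config, "optsne_config"))
    stop("`config` must come from embedding_config()")
  x <- as_numeric_matrix(data)
  check_finite(x)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 points")

  eta <- if (identical(config$eta, "auto"))
    auto_learning_rate(n, config$alpha) else config$eta
  ls_flag <- check_ls_condition(n, config$alpha, eta)
  if (identical(ls_flag, "WARN"))
    warning(sprintf(
      "alpha * eta = %g exceeds n = %d: gradient descent may be unstable (irregular KLD peaks); proceeding",
      config$alpha * eta, n))

  if (is.null(affinities)) {
    affinities <- symmetrize_affinities(build_conditional_affinities(
      x, config$perplexity, k_neighbors = config$k_neighbors))
  } else {
    if (!inherits(affinities, "optsne_affinities"))
      stop("`affinities` must be an optsne_affinities object")
    if (affinities$n != n)
      stop("`affinities` were built for a different number of points")
    if (affinities$exaggeration != 1)
      stop("`affinities` must be unexaggerated (exaggeration factor 1)")
    if (!isTRUE(all.equal(affinities$perplexity, config$perplexity)))
      warning("`affinities` perplexity differs from the config; using the precomputed model")
  }

  # upper-triangle pair list: P is exactly symmetric, so each stored
  # unordered pair drives both directions in the compiled kernel
  tr <- affinity_triplets(affinities)
  keep <- tr$i < tr$j
  tr <- list(i = tr$i[keep], j = tr$j[keep], x = tr$x[keep])
  px_base <- tr$x                       # sums to 1/2 (upper triangle)
  px <- px_base * config$alpha          # exaggerated phase
  spl <- 2 * sum_p_log_p(px)            # full-matrix sum p log p

  y <- with_seed(config$seed, matrix(rnorm(n * 2L, sd = 1e-4), n, 2L))
  velocity <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)

  max_it <- config$max_iterations
  kld_trace <- rep(NA_real_, max_it)
  kldrc_trace <- rep(NA_real_, max_it)
  phase_trace <- character(max_it)
  phase <- "EE"
  ee_stop_iteration <- NA_integer_
  kldrc_peak_iteration <- NA_integer_
  consec <- 0L
  total <- max_it

  con <- NULL
  if (!is.null(trace_file)) {
    con <- file(trace_file, open = "wt")
    on.exit(close(con), add = TRUE)
    writeLines("iteration\tphase\tkld\tkldrc\tgain_mean\tgain_max", con)
  }

  for (iter in seq_len(max_it)) {
    step <- cpp_gradient_kld(tr$i, tr$j, px, y, config$theta, spl, TRUE)
    if (!is.finite(step$kld) || !all(is.finite(step$grad)))
      stop(sprintf("non-finite gradient/KLD at iteration %d; aborting", iter))

    momentum <- if (phase == "EE") config$momentum_early
                else config$momentum_late
    upd <- jacobs_update(y, velocity, gains, step$grad, momentum, eta)
    velocity <- upd$velocity
    gains <- upd$gains
    y <- sweep(upd$coords, 2L, colMeans(upd$coords), "-")
    if (!all(is.finite(y)))
      stop(sprintf("non-finite coordinates at iteration %d; aborting (learning rate too large?)", iter))

    kld_trace[iter] <- step$kld
    kldrc_trace[iter] <- if (iter >= 2L)
      kldrc(kld_trace[iter - 1L], kld_trace[iter]) else NA_real_
    phase_trace[iter] <- phase

    if (!is.null(con))
      writeLines(sprintf("%d\t%s\t%.10g\t%.6g\t%.4g\t%.4g", iter, phase,
                         step$kld, kldrc_trace[iter], mean(gains),
                         max(gains)), con)
    if (verbose && iter %% 50L == 0L)
      message(sprintf("iter %d [%s] KLD = %.4f", iter, phase, step$kld))

    if (phase == "EE") {
      stop_ee <- FALSE
      if (identical(config$ee_stop, "auto")) {
        det <- detect_max_kldrc(kldrc_trace[seq_len(iter)],
                                config$min_ee_iterations,
                                config$kldrc_patience)
        if (det$fired) {
          stop_ee <- TRUE
          kldrc_peak_iteration <- det$peak_iteration
        }
      } else if (iter >= config$ee_stop) {
        stop_ee <- TRUE
      }
      if (stop_ee) {
        px <- px_base                     # instantaneous removal
        spl <- 2 * sum_p_log_p(px)
        phase <- "POST_EE"
        ee_stop_iteration <- iter
      }
    } else if (config$termination_divisor > 0 &&
               iter >= ee_stop_iteration + config$min_post_ee_iterations + 2L) {
      if (check_termination(kld_trace[iter - 1L], kld_trace[iter],
                            config$termination_divisor)) {
        consec <- consec + 1L
        if (consec >= config$termination_consecutive) {
          total <- iter
          break
        }
      } else {
        consec <- 0L
      }
    }
  }

  if (phase == "EE")
    warning("early exaggeration was never removed within max_iterations; endpoint KLD is undefined")

  keep <- seq_len(total)
  endpoint_kld <- if (phase == "POST_EE" && total > ee_stop_iteration)
    kld_trace[total] else NA_real_

  structure(
    list(coords = y,
         kld_trace = kld_trace[keep],
         kldrc_trace = kldrc_trace[keep],
         phase_trace = phase_trace[keep],
         ee_stop_iteration = ee_stop_iteration,
         kldrc_peak_iteration = kldrc_peak_iteration,
         total_iterations = total,
         endpoint_kld = endpoint_kld,
         eta = eta,
         ls_flag = ls_flag,
         config = config,
         seed = config$seed,
         data_fingerprint = data_fingerprint(x)),
    class = "optsne_result")
}

data_fingerprint <- function(x) {
  list(n = nrow(x), d = ncol(x), sum = sum(x), sumsq = sum(x^2))
}

#' @method print optsne_result
#' @export
print.optsne_result <- function(x, ...) {
  cat(sprintf(
    paste0("opt-SNE embedding: n = %d, %d iterations ",
           "(EE removed after %s), endpoint KLD = %s, eta = %g, seed = %d\n"),
    nrow(x$coords), x$total_iterations,
    ifelse(is.na(x$ee_stop_iteration), "never",
           as.character(x$ee_stop_iteration)),
    ifelse(is.na(x$endpoint_kld), "NA", sprintf("%.4f", x$endpoint_kld)),
    x$eta, x$seed))
  invisible(x)
}

#' @method print optsne_config
#' @export
print.optsne_config <- function(x, ...) {
  cat(sprintf(
    paste0("opt-SNE config: perplexity %g, alpha %g, eta %s, theta %g, ",
           "EE stop %s, termination X = %g, max %d iterations, seed %d\n"),
    x$perplexity, x$alpha,
    if (identical(x$eta, "auto")) "auto (n/alpha)" else format(x$eta),
    x$theta,
    if (identical(x$ee_stop, "auto")) "auto (maxKLDRC)" else format(x$ee_stop),
    x$termination_divisor, x$max_iterations, x$seed))
  invisible(x)
}
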