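#' Specify one synthetic cell population
#'
#' Populations live on the asinh (post-transform) intensity scale: a
#' (optionally correlated) Gaussian around a per-channel centroid, with a
#' relative frequency in the panel.
#'
#' @param name class label.
#' @param frequency fraction of events in `(0, 1]`.
#' @param centroid per-channel mean (asinh-scale arbitrary units).
#' @param spread per-channel standard deviation (recycled if scalar).
#' @param correlation optional channel-pair correlation matrix (symmetric,
#'   positive semi-definite, unit diagonal).
#' @export
population_spec <- function(name, frequency, centroid, spread,
                            correlation = NULL) {
  if (!is_scalar_number(frequency) || frequency <= 0 || frequency > 1)
    stop("`frequency` must be in (0, 1]")
  centroid <- as.numeric(centroid)
  k <- length(centroid)
  spread <- rep_len(as.numeric(spread), k)
  if (any(spread <= 0)) stop("`spread` must be positive")
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (nrow(correlation) != k || ncol(correlation) != k)
      stop("`correlation` must be a square matrix matching the channels")
    if (max(abs(correlation - t(correlation))) > 1e-8)
      stop("`correlation` must be symmetric")
    if (min(eigen(correlation, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8)
      stop("`correlation` must be positive semi-definite")
  }
  structure(list(name = as.character(name), frequency = frequency,
                 centroid = centroid, spread = spread,
                 correlation = correlation),
            class = "population_spec")
}

#' Default synthetic cytometry panel
#'
#' Builds a panel of populations whose centroids sit on a bimodal
#' negative/positive marker grid (each population is "positive" on a
#' random subset of channels, emulating on/off marker signatures), scaled
#' by `separation`. One population is assigned the rare frequency; the
#' remaining mass is split unevenly (weights proportional to 1/rank)
#' across the others, as typical of real panels. The default recipe
#' (10 populations on 11 channels with one 0.5% subset) mirrors the scale
#' of an 11-lineage-marker flow panel and is the package's canonical test
#' fixture.
#'
#' @param n_populations number of populations, `>= 2`.
#' @param n_channels number of measured channels.
#' @param rare_fraction frequency of the rare population; must be below
#'   `1 / n_populations`.
#' @param separation distance between the negative and positive marker
#'   levels in asinh units; `0` collapses all centroids.
#' @param spread within-population standard deviation per channel.
#' @param panel_seed seed for the signature draw (the panel itself is a
#'   deterministic fixture).
#' @return list of [population_spec()] objects (class `optsne_panel`),
#'   with the channel count and spread attached as attributes.
#' @export
default_cytometry_panel <- function(n_populations = 10L, n_channels = 11L,
                                    rare_fraction = 0.005, separation = 5,
                                    spread = 0.25, panel_seed = 1L) {
  n_populations <- as.integer(n_populations)
  if (n_populations < 2L) stop("need at least 2 populations")
  if (rare_fraction >= 1 / n_populations)
    stop(sprintf(
      "rare_fraction = %g must be below 1/n_populations = %g",
      rare_fraction, 1 / n_populations))

  patterns <- with_seed(panel_seed, {
    pat <- matrix(0L, n_populations, n_channels)
    taken <- character(0)
    for (p in seq_len(n_populations)) {
      repeat {
        n_pos <- sample(seq(2L, max(3L, n_channels %/% 2L)), 1L)
        row <- integer(n_channels)
        row[sample.int(n_channels, n_pos)] <- 1L
        key <- paste(row, collapse = "")
        if (!key %in% taken) break
      }
      taken <- c(taken, key)
      pat[p, ] <- row
    }
    pat
  })

  main <- n_populations - 1L
  w <- 1 / seq_len(main)
  freqs <- c(w / sum(w) * (1 - rare_fraction), rare_fraction)
  names_ <- c(sprintf("pop%02d", seq_len(main)), "rare")

  panel <- lapply(seq_len(n_populations), function(p)
    population_spec(names_[p], freqs[p],
                    centroid = patterns[p, ] * separation,
                    spread = spread))
  structure(panel, class = c("optsne_panel", "list"),
            n_channels = n_channels, spread = spread,
            separation = separation)
}

#' Generate a labeled synthetic cytometry mixture
#'
#' Population sizes are drawn multinomially from the panel frequencies
#' (so rare-class Poisson variability is exercised); events are Gaussian
#' around each population centroid on the asinh scale, optionally with
#' channel-channel correlation, and finally shuffled. Bit-identical for a
#' given seed.
#'
#' @param panel list of [population_spec()] objects; frequencies must sum
#'   to 1 (within 1e-9).
#' @param n_events number of events, `>= 10`.
#' @param seed integer seed.
#' @return a `labeled_dataset`: event x channel `matrix`, `channels`,
#'   per-event `labels` (factor), provenance, and the seed.
#' @export
generate_mixture <- function(panel, n_events, seed = 1L) {
  if (inherits(panel, "population_spec")) panel <- list(panel)
  if (!all(vapply(panel, inherits, logical(1), "population_spec")))
    stop("`panel` must be a list of population_spec objects")
  n_events <- as.integer(n_events)
  if (n_events < 10L) stop("`n_events` must be at least 10")
  freqs <- vapply(panel, `[[`, numeric(1), "frequency")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("panel frequencies must sum to 1")
  k <- length(panel[[1]]$centroid)
  if (!all(vapply(panel, function(p) length(p$centroid), integer(1)) == k))
    stop("all populations must share the same number of channels")

  with_seed(seed, {
    counts <- as.vector(rmultinom(1L, n_events, freqs))
    blocks <- vector("list", length(panel))
    for (p in seq_along(panel)) {
      cnt <- counts[p]
      if (cnt == 0L) { blocks[[p]] <- matrix(numeric(0), 0L, k); next }
      z <- matrix(rnorm(cnt * k), cnt, k)
      spec <- panel[[p]]
      if (is.null(spec$correlation)) {
        x <- sweep(z, 2L, spec$spread, "*")
      } else {
        sig <- diag(spec$spread) %*% spec$correlation %*% diag(spec$spread)
        e <- eigen(sig, symmetric = TRUE)
        x <- z %*% t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), k))
      }
      blocks[[p]] <- sweep(x, 2L, spec$centroid, "+")
    }
    mat <- do.call(rbind, blocks)
    labels <- factor(rep(vapply(panel, `[[`, character(1), "name"), counts),
                     levels = vapply(panel, `[[`, character(1), "name"))
    ord <- sample.int(n_events)
    mat <- mat[ord, , drop = FALSE]
    labels <- labels[ord]
  })

  channels <- sprintf("ch%02d", seq_len(k))
  colnames(mat) <- channels
  structure(
    list(matrix = mat, channels = channels, labels = labels,
         transforms_applied = character(0),
         provenance = list(source = "synthetic mixture",
                           populations = vapply(panel, `[[`, character(1),
                                                "name"),
                           frequencies = freqs, n_events = n_events,
                           seed = seed),
         seed = seed),
    class = "labeled_dataset")
}

#' @method print labeled_dataset
#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled dataset: %d events x %d channels%s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", nlevels(x$labels))))
  if (length(x$transforms_applied))
    cat("transforms:", paste(x$transforms_applied, collapse = "; "), "\n")
  invisible(x)
}

#' Synthetic KLD trace fixtures
#'
#' Parametric KLD-over-iteration traces for exercising the KLDRC peak
#' detector without running an embedding:
#' \describe{
#'   \item{plateau_then_descent}{the canonical morphology: the relative
#'     rate of KLD change ramps up linearly to a peak (end of the plateau)
#'     and decays back to a small residual descent. The KLDRC peak index
#'     of the noise-free trace is attached as `attr(, "peak_iteration")`.}
#'   \item{monotone}{constant-ratio decay, i.e. constant KLDRC with no
#'     local maximum.}
#'   \item{spiky}{the plateau shape corrupted by sporadic upward KLD
#'     spikes, mimicking an unstable, overly large learning rate.}
#' }
#' Noise is multiplicative Gaussian, `noise_sd` being the standard
#' deviation as a fraction of the local KLD value (real traces from a
#' deterministic descent are smooth; per-iteration jitter around 0.1% of
#' the KLD is already pessimistic).
#'
#' @param shape one of `"plateau_then_descent"`, `"monotone"`, `"spiky"`.
#' @param length trace length, `>= 10`.
#' @param noise_sd relative noise standard deviation (0 = clean).
#' @param seed seed for the noise (and spikes).
#' @param peak_at iteration of the KLDRC peak for the plateau shape
#'   (default `floor(length * 0.45)`).
#' @param peak_kldrc KLDRC value at the peak, percent (default 6).
#' @return numeric KLD trace with attributes `shape`, `clean` (the
#'   noise-free trace) and, for the plateau shape, `peak_iteration`.
#' @export
synth_kld_trace <- function(shape = c("plateau_then_descent", "monotone",
                                      "spiky"),
                            length = 120L, noise_sd = 0, seed = 1L,
                            peak_at = NULL, peak_kldrc = 6) {
  shape <- match.arg(shape)
  length <- as.integer(length)
  if (length < 10L) stop("`length` must be at least 10")

  t <- seq_len(length)
  if (shape == "monotone") {
    clean <- 5 * 0.99^(t - 1)
    peak <- NA_integer_
  } else {
    if (is.null(peak_at)) peak_at <- as.integer(floor(length * 0.45))
    # per-iteration relative decrease (percent): linear ramp to the peak,
    # then linear decay to a residual slow descent
    rc <- ifelse(t <= peak_at, peak_kldrc * t / peak_at,
                 pmax(0.3, peak_kldrc * (1 - (t - peak_at) / (0.25 * length))))
    clean <- 5 * cumprod(1 - c(0, rc[-1]) / 100)
    rc_clean <- c(NA_real_, kldrc(clean[-length], clean[-1]))
    peak <- which.max(replace(rc_clean, is.na(rc_clean), -Inf))
  }

  trace <- clean
  if (shape == "spiky") {
    trace <- with_seed(seed + 1L, {
      idx <- sample(seq(10L, length - 1L), max(3L, length %/% 30L))
      trace[idx] <- trace[idx] * 1.5
      trace
    })
  }
  if (noise_sd > 0) {
    trace <- with_seed(seed,
                       pmax(trace * (1 + rnorm(length, 0, noise_sd)), 1e-6))
  }

  structure(trace, shape = shape, clean = clean,
            peak_iteration = if (shape == "plateau_then_descent") peak
                             else NA_integer_)
}
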