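#' Gradient-descent settings for the embedding engine
#'
#' Bundles the knobs of the Barnes-Hut gradient and the Jacobs
#' (delta-bar-delta) adaptive step. Gains grow additively by
#' `gain_increase` while a coordinate keeps moving in a stable direction
#' (gradient sign opposite to the velocity sign), shrink multiplicatively
#' by `gain_decay` otherwise, and never drop below `gain_floor`.
#'
#' @param theta Barnes-Hut opening parameter in `[0, 1)`; `0` selects the
#'   exact O(n^2) gradient.
#' @param eta initial learning-rate step size.
#' @param alpha early exaggeration factor carried for bookkeeping.
#' @param momentum_early,momentum_late momentum during and after the early
#'   exaggeration phase.
#' @param gain_increase,gain_decay,gain_floor Jacobs scheme constants.
#' @export
gradient_settings <- function(theta = 0.5, eta = 200, alpha = 12,
                              momentum_early = 0.5, momentum_late = 0.8,
                              gain_increase = 0.2, gain_decay = 0.8,
                              gain_floor = 0.01) {
  if (!is_scalar_number(theta) || theta < 0 || theta >= 1)
    stop("`theta` must be in [0, 1)")
  if (!is_scalar_number(eta) || eta <= 0) stop("`eta` must be positive")
  structure(list(theta = theta, eta = eta, alpha = alpha,
                 momentum_early = momentum_early,
                 momentum_late = momentum_late,
                 gain_increase = gain_increase, gain_decay = gain_decay,
                 gain_floor = gain_floor),
            class = "optsne_gradient_settings")
}

#' Embedding-space distribution and KLD at given coordinates
#'
#' Computes the Kullback-Leibler divergence
#' \eqn{\sum_{ij} p_{ij} \log(p_{ij}/q_{ij})} over the stored affinity
#' pairs, where \eqn{q_{ij} = (1 + \|y_i - y_j\|^2)^{-1} / Z} is the
#' Cauchy (Student-t, 1 df) embedding similarity. The normalisation `Z` is
#' exact for `theta = 0` and Barnes-Hut-approximated for `theta > 0`. When
#' `P` is exaggerated, the exaggerated entries enter the sum, so the KLD is
#' inflated during the early exaggeration phase.
#'
#' @param P an `optsne_affinities` object (possibly exaggerated).
#' @param coords n x 2 matrix of embedding coordinates.
#' @param theta Barnes-Hut opening parameter.
#' @return list with elements `kld` and `Z`.
#' @export
compute_q_and_kld <- function(P, coords, theta = 0.5) {
  coords <- as.matrix(coords)
  check_finite(coords, "coords")
  tr <- affinity_triplets(P)
  res <- cpp_gradient_kld(tr$i, tr$j, tr$x, coords, theta,
                          sum_p_log_p(tr$x), FALSE)
  list(kld = res$kld, Z = res$Z)
}

#' t-SNE gradient (exact or Barnes-Hut)
#'
#' Returns the gradient `4 * (F_attr - F_rep)` of the KLD with respect to
#' the embedding coordinates: attraction summed over the stored affinity
#' pairs (alpha-scaled automatically when `P` is exaggerated), repulsion
#' via a quadtree with opening criterion `cell size / distance < theta`
#' (exact double loop when `theta = 0`). Coincident points are kept finite
#' by the package-wide squared-distance floor.
#'
#' @inheritParams compute_q_and_kld
#' @return n x 2 gradient matrix.
#' @export
tsne_gradient <- function(P, coords, theta = 0.5) {
  coords <- as.matrix(coords)
  check_finite(coords, "coords")
  tr <- affinity_triplets(P)
  cpp_gradient_kld(tr$i, tr$j, tr$x, coords, theta, 0, FALSE)$grad
}

# Constant KLD term over stored affinity entries (floored inside the log);
# recomputed only when P changes, i.e. at (de-)exaggeration.
sum_p_log_p <- function(px) sum(px * log(pmax(px, .prob_floor)))

#' Initialize an optimization state
#'
#' @param coords n x 2 starting coordinates.
#' @return an `optsne_state` with zero velocity, unit gains, iteration 0,
#'   phase `"EE"`, and empty KLD/KLDRC traces.
#' @export
optimization_state <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("embedding coordinates must be n x 2")
  check_finite(coords, "coords")
  structure(
    list(coords = coords,
         velocity = matrix(0, nrow(coords), 2L),
         gains = matrix(1, nrow(coords), 2L),
         iteration = 0L,
         phase = "EE",
         kld_trace = numeric(0),
         kldrc_trace = numeric(0)),
    class = "optsne_state")
}

#' One Jacobs adaptive-gain gradient-descent update
#'
#' Per coordinate: the gain increases additively when the current gradient
#' sign disagrees with the velocity sign (a stable descent direction under
#' the delta-bar-delta rule), otherwise shrinks multiplicatively, floored
#' at `gain_floor`. The update is
#' `momentum * velocity - eta * gain * grad`; it is added to the
#' coordinates and becomes the new velocity. Momentum is `momentum_early`
#' in the `"EE"` phase and `momentum_late` afterwards. Recentering is the
#' caller's concern (see [run_optsne()]), keeping this step a pure update.
#'
#' @param state an `optsne_state`.
#' @param grad n x 2 gradient matrix.
#' @param settings a [gradient_settings()] object.
#' @return the advanced state.
#' @export
jacobs_step <- function(state, grad, settings = gradient_settings()) {
  if (!inherits(state, "optsne_state")) stop("`state` must be an optsne_state")
  grad <- as.matrix(grad)
  stopifnot(identical(dim(grad), dim(state$coords)))

  momentum <- if (identical(state$phase, "EE")) settings$momentum_early
              else settings$momentum_late
  upd <- jacobs_update(state$coords, state$velocity, state$gains, grad,
                       momentum, settings$eta, settings$gain_increase,
                       settings$gain_decay, settings$gain_floor)
  state$coords <- upd$coords
  state$velocity <- upd$velocity
  state$gains <- upd$gains
  state$iteration <- state$iteration + 1L
  state
}

# The delta-bar-delta update itself; shared by jacobs_step() and the
# run_optsne() inner loop.
jacobs_update <- function(coords, velocity, gains, grad, momentum, eta,
                          gain_increase = 0.2, gain_decay = 0.8,
                          gain_floor = 0.01) {
  agree <- sign(grad) == sign(velocity)
  gains <- pmax(ifelse(agree, gains * gain_decay, gains + gain_increase),
                gain_floor)
  velocity <- momentum * velocity - eta * gains * grad
  list(coords = coords + velocity, velocity = velocity, gains = gains)
}
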