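#' Perplexity-calibrated conditional neighbour distributions
#'
#' Builds, for every event, a Gaussian conditional distribution over its
#' `k_neighbors` exact nearest neighbours in the (already transformed) input
#' space. The per-point bandwidth \eqn{\sigma_i} is found by bisection so
#' that the perplexity \eqn{2^{H(P_{\cdot|i})}} of each conditional
#' distribution matches the target, where \eqn{H} is Shannon entropy in
#' bits. Perplexity acts as a soft effective number of nearest neighbours.
#'
#' Distances are squared Euclidean on the input matrix as given; channel
#' scaling/transforms are applied upstream (see [apply_transform()]).
#' Nearest neighbours are exact (kd-tree search), so the sparse result is
#' directly comparable to a dense all-pairs computation.
#'
#' @param data numeric event x channel matrix (or a `labeled_dataset`).
#' @param perplexity positive real, must be smaller than `n - 1`.
#' @param k_neighbors neighbour list size; defaults to
#'   `floor(3 * perplexity)`, the conventional Barnes-Hut truncation.
#' @param tol bisection tolerance on entropy (nats); default `1e-5`.
#' @param max_iter maximum bisection iterations per point; default 200. On
#'   non-convergence (e.g. duplicate-heavy neighbourhoods) the final
#'   bandwidth is kept and a warning is emitted.
#' @return an object of class `optsne_conditionals`: neighbour index matrix,
#'   conditional probability matrix (rows sum to 1), per-point bandwidths
#'   `sigma`, and calibration metadata.
#' @seealso [symmetrize_affinities()], [exaggerate()]
#' @export
build_conditional_affinities <- function(data, perplexity, k_neighbors = NULL,
                                         tol = 1e-5, max_iter = 200L) {
  x <- as_numeric_matrix(data)
  check_finite(x)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 points to build affinities")
  if (!is_scalar_number(perplexity) || perplexity <= 0)
    stop("`perplexity` must be a positive number")
  if (perplexity >= n - 1)
    stop(sprintf(
      "perplexity = %g is too large for n = %d; it must be smaller than n - 1 = %d",
      perplexity, n, n - 1L))

  if (is.null(k_neighbors)) {
    k_neighbors <- floor(3 * perplexity)
    if (k_neighbors >= n)
      stop(sprintf(
        "default neighbour list floor(3 * perplexity) = %d does not fit n = %d; pass k_neighbors < n explicitly or lower the perplexity",
        k_neighbors, n))
  }
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors <= perplexity)
    stop(sprintf(
      "k_neighbors = %d cannot calibrate perplexity %g; need k_neighbors > perplexity",
      k_neighbors, perplexity))
  if (k_neighbors > n - 1L)
    stop(sprintf("k_neighbors = %d exceeds the n - 1 = %d available neighbours",
                 k_neighbors, n - 1L))

  nn <- FNN::get.knn(x, k = k_neighbors)
  cal <- cpp_perplexity_search(nn$nn.dist^2, perplexity, tol,
                               as.integer(max_iter))
  if (!all(cal$converged))
    warning(sprintf(
      "bandwidth bisection did not converge for %d point(s) (degenerate, duplicate-heavy neighbourhoods?); final sigma kept",
      sum(!cal$converged)))

  structure(
    list(index = nn$nn.index,
         prob = cal$prob,
         bandwidths = sqrt(1 / (2 * cal$beta)),
         perplexity = perplexity,
         k_neighbors = k_neighbors,
         n = n,
         converged = cal$converged),
    class = "optsne_conditionals")
}

#' Symmetrize conditional distributions into the joint affinity model
#'
#' Standard t-SNE symmetrization
#' \eqn{p_{ij} = (p_{j|i} + p_{i|j}) / (2n)}, stored sparse. The stored
#' entries sum to 1 and the matrix is exactly symmetric.
#'
#' @param conditionals result of [build_conditional_affinities()].
#' @return an `optsne_affinities` object holding the sparse symmetric
#'   matrix `P` (a [Matrix::dgCMatrix-class]), the perplexity, per-point
#'   bandwidths, and the current exaggeration factor (1 = unexaggerated).
#' @export
symmetrize_affinities <- function(conditionals) {
  if (!inherits(conditionals, "optsne_conditionals"))
    stop("`conditionals` must come from build_conditional_affinities()")
  n <- conditionals$n
  k <- conditionals$k_neighbors
  pc <- Matrix::sparseMatrix(i = rep(seq_len(n), times = k),
                             j = as.vector(conditionals$index),
                             x = as.vector(conditionals$prob),
                             dims = c(n, n))
  p <- (pc + Matrix::t(pc)) / (2 * n)

  structure(
    list(P = methods::as(p, "CsparseMatrix"),
         perplexity = conditionals$perplexity,
         bandwidths = conditionals$bandwidths,
         k_neighbors = k,
         n = n,
         exaggeration = 1),
    class = "optsne_affinities")
}

#' Apply (early) exaggeration to an affinity model
#'
#' Multiplies every stored \eqn{p_{ij}} by `alpha` without renormalizing, so
#' the global sum becomes `alpha`. The exaggeration factor is recorded on
#' the model and carries into both the gradient (stronger attraction) and
#' the KLD, which is therefore inflated during the exaggerated phase.
#'
#' @param model an `optsne_affinities` object.
#' @param alpha exaggeration factor, must be `>= 1` (`1` is the identity).
#' @return the exaggerated model.
#' @export
exaggerate <- function(model, alpha) {
  if (!inherits(model, "optsne_affinities"))
    stop("`model` must be an optsne_affinities object")
  if (!is_scalar_number(alpha) || alpha < 1)
    stop("`alpha` must be a single number >= 1")
  model$P <- model$P * alpha
  model$exaggeration <- model$exaggeration * alpha
  model
}

# 0-based triplet view of the sparse affinity matrix, the form consumed by
# the compiled gradient/KLD kernel.
affinity_triplets <- function(model) {
  tp <- methods::as(model$P, "TsparseMatrix")
  list(i = tp@i, j = tp@j, x = tp@x)
}

#' @method print optsne_affinities
#' @export
print.optsne_affinities <- function(x, ...) {
  cat(sprintf(
    "opt-SNE affinity model: n = %d, perplexity = %g, k = %d, nnz = %d, exaggeration = %g\n",
    x$n, x$perplexity, x$k_neighbors, length(x$P@x), x$exaggeration))
  invisible(x)
}
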