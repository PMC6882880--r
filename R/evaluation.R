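#' Configuration of the 1NN embedding-quality protocol
#'
#' Per repeat, a uniform pseudorandom training sample and a disjoint test
#' sample are drawn from the embedding and every test point is classified
#' by its single nearest training neighbour in the 2-D plane. The repeat
#' seeds are kept fixed so that compared embeddings of the same dataset
#' score the same cells.
#'
#' @param n_train training-set size, default 10000.
#' @param n_test test-set size, default 50000.
#' @param repeats number of repeats averaged, default 5.
#' @param seeds integer seed per repeat; default `seq_len(repeats)`.
#' @export
knn_protocol_config <- function(n_train = 10000L, n_test = 50000L,
                                repeats = 5L, seeds = NULL) {
  repeats <- as.integer(repeats)
  if (is.null(seeds)) seeds <- seq_len(repeats)
  if (length(seeds) != repeats)
    stop("`seeds` must contain one seed per repeat")
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 repeats = repeats, seeds = as.integer(seeds)),
            class = "optsne_knn_config")
}

# Index of the nearest training point for every test point (2-D Euclidean),
# exact kd-tree lookup with ties broken by the lowest training index.
nn1_index <- function(train, test) {
  k <- min(2L, nrow(train))
  nn <- FNN::get.knnx(train, test, k = k)
  idx <- nn$nn.index[, 1L]
  if (k == 2L) {
    tie <- nn$nn.dist[, 1L] == nn$nn.dist[, 2L]
    if (any(tie))
      idx[tie] <- pmin(nn$nn.index[tie, 1L], nn$nn.index[tie, 2L])
  }
  idx
}

#' 1-nearest-neighbour classification accuracy of an embedding
#'
#' The embedding-quality score: how often a held-out event's nearest
#' training neighbour in the 2-D embedding shares its ground-truth class.
#' Sampling is index-based from the seeded generator applied to the input
#' (canonical) event ordering, so identical seed lists reproduce the
#' report exactly. When the embedding has fewer events than
#' `n_train + n_test`, both samples shrink proportionally, preserving the
#' 1:5 train:test ratio, with a warning. Classes absent from a repeat's
#' test sample are flagged, not silently dropped.
#'
#' @param embedding n x 2 coordinate matrix or an `optsne_result`.
#' @param labels ground-truth class per event (coerced to factor).
#' @param cfg a [knn_protocol_config()].
#' @return an `optsne_accuracy` report: `overall` (mean over repeats),
#'   `per_class` (mean over the repeats in which the class was sampled),
#'   `per_repeat` (per-seed overall accuracies), the per-repeat per-class
#'   matrix, and the count of repeats missing each class.
#' @export
knn1_accuracy <- function(embedding, labels, cfg = knn_protocol_config()) {
  y <- if (inherits(embedding, "optsne_result")) embedding$coords
       else as.matrix(embedding)
  n <- nrow(y)
  labels <- as.factor(labels)
  if (length(labels) != n)
    stop("`labels` must provide one class per embedded event")
  if (n < 4L) stop("need at least 4 events")

  n_train <- cfg$n_train
  n_test <- cfg$n_test
  if (n < n_train + n_test) {
    ratio <- cfg$n_test / cfg$n_train
    n_train <- max(1L, as.integer(floor(n / (1 + ratio))))
    n_test <- min(n - n_train, as.integer(floor(n_train * ratio)))
    warning(sprintf(
      "embedding has n = %d < n_train + n_test = %d; scaled down to %d train / %d test (ratio preserved)",
      n, cfg$n_train + cfg$n_test, n_train, n_test))
  }

  classes <- levels(labels)
  per_repeat <- numeric(cfg$repeats)
  per_class_mat <- matrix(NA_real_, cfg$repeats, length(classes),
                          dimnames = list(NULL, classes))

  for (r in seq_len(cfg$repeats)) {
    with_seed(cfg$seeds[r], {
      train_idx <- sample.int(n, n_train)
      rest <- setdiff(seq_len(n), train_idx)
      test_idx <- if (length(rest) == n_test) rest
                  else rest[sample.int(length(rest), n_test)]
    })
    pred <- labels[train_idx][nn1_index(y[train_idx, , drop = FALSE],
                                        y[test_idx, , drop = FALSE])]
    truth <- labels[test_idx]
    per_repeat[r] <- mean(pred == truth)
    hits <- tapply(pred == truth, truth, mean)
    per_class_mat[r, names(hits)] <- hits
  }

  missing <- colSums(is.na(per_class_mat))
  if (any(missing > 0))
    warning(sprintf(
      "class(es) absent from some test samples (flagged in the report): %s",
      paste(classes[missing > 0], collapse = ", ")))

  structure(
    list(overall = mean(per_repeat),
         per_class = colMeans(per_class_mat, na.rm = TRUE),
         per_repeat = data.frame(repeat_id = seq_len(cfg$repeats),
                                 seed = cfg$seeds, overall = per_repeat),
         per_class_by_repeat = per_class_mat,
         missing_in_repeats = missing,
         n_train = n_train, n_test = n_test,
         config = cfg),
    class = "optsne_accuracy")
}

#' @method print optsne_accuracy
#' @export
print.optsne_accuracy <- function(x, ...) {
  cat(sprintf("1NN accuracy: overall %.4f over %d repeats (%d train / %d test)\n",
              x$overall, x$config$repeats, x$n_train, x$n_test))
  cat("per class:\n")
  print(round(x$per_class, 4))
  invisible(x)
}

#' Tidy table view of a 1NN accuracy report
#'
#' One row per class per repeat, plus overall rows, suitable for writing
#' as a tab-separated report.
#'
#' @param report an `optsne_accuracy` object.
#' @return a data.frame with columns repeat_id, seed, class, accuracy,
#'   present.
#' @export
accuracy_table <- function(report) {
  if (!inherits(report, "optsne_accuracy"))
    stop("`report` must be an optsne_accuracy object")
  cls <- colnames(report$per_class_by_repeat)
  rows <- lapply(seq_len(nrow(report$per_class_by_repeat)), function(r) {
    data.frame(repeat_id = r, seed = report$config$seeds[r],
               class = c(cls, "overall"),
               accuracy = c(report$per_class_by_repeat[r, ],
                            report$per_repeat$overall[r]),
               present = c(!is.na(report$per_class_by_repeat[r, ]), TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a 1NN accuracy report as a tab-separated file
#'
#' @param report an `optsne_accuracy` object.
#' @param path output file path.
#' @export
write_accuracy_report <- function(report, path) {
  data.table::fwrite(accuracy_table(report), path, sep = "\t")
  invisible(path)
}

#' Compare endpoint KLD across configurations
#'
#' Summarizes, per configuration, the endpoint (final unexaggerated) KLD
#' over seed replicates as mean +/- SEM; a lower mean flags the
#' higher-fidelity embedding. All results must come from identical input
#' data (checked via the stored data fingerprints).
#'
#' @param results a named list of configurations, each a list of
#'   `optsne_result` objects from different seeds on the same data.
#' @return a data.frame with one row per configuration: n_runs, mean, SEM,
#'   median, min, max of the endpoint KLD, ordered as given; the
#'   configuration with the lowest mean is marked in the `best` column.
#' @export
compare_endpoint_kld <- function(results) {
  if (!is.list(results) || is.null(names(results)) ||
      any(!nzchar(names(results))))
    stop("`results` must be a named list: one element per configuration")
  flat <- unlist(results, recursive = FALSE)
  if (!all(vapply(flat, inherits, logical(1), "optsne_result")))
    stop("every element must contain optsne_result objects")

  fps <- lapply(flat, `[[`, "data_fingerprint")
  if (length(unique(vapply(fps, function(f)
    paste(f$n, f$d, format(f$sum, digits = 15), format(f$sumsq, digits = 15)),
    character(1)))) != 1L)
    stop("mismatched data fingerprints: endpoint KLDs are only comparable on identical data")

  rows <- lapply(names(results), function(nm) {
    kl <- vapply(results[[nm]], `[[`, numeric(1), "endpoint_kld")
    if (any(!is.finite(kl)))
      stop(sprintf("configuration '%s' has runs without a defined endpoint KLD", nm))
    data.frame(config = nm, n_runs = length(kl),
               mean_endpoint_kld = mean(kl),
               sem_endpoint_kld = if (length(kl) > 1) sd(kl) / sqrt(length(kl)) else 0,
               median_endpoint_kld = stats::median(kl),
               min_endpoint_kld = min(kl), max_endpoint_kld = max(kl))
  })
  out <- do.call(rbind, rows)
  out$best <- out$mean_endpoint_kld == min(out$mean_endpoint_kld)
  out
}
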