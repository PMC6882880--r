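#' Per-channel intensity transform specification
#'
#' Cytometry intensities are variance-stabilized before embedding:
#' `asinh` with a channel-type cofactor (5 is customary for mass
#' cytometry, 150 for fluorescence), `log10` for light-scatter channels
#' (floored at `log_floor` since zeros occur), or `none`. All transforms
#' are strictly monotone per channel.
#'
#' @param kind `"asinh"`, `"log10"` or `"none"`; either a single value for
#'   all channels or a named character vector mapping channel names to
#'   kinds.
#' @param cofactor positive asinh cofactor, default 150 (fluorescence).
#' @param log_floor values below this are clamped before `log10`,
#'   default 1.
#' @export
transform_spec <- function(kind = "asinh", cofactor = 150, log_floor = 1) {
  kinds <- c("asinh", "log10", "none")
  if (!all(kind %in% kinds))
    stop("`kind` entries must be one of: ", paste(kinds, collapse = ", "))
  if (any(kind == "asinh") && (!is_scalar_number(cofactor) || cofactor <= 0))
    stop("`cofactor` must be a positive number")
  structure(list(kind = kind, cofactor = cofactor, log_floor = log_floor),
            class = "transform_spec")
}

#' Apply intensity transforms to a dataset
#'
#' asinh channels map `x -> asinh(x / cofactor)`; log channels map
#' `x -> log10(max(x, log_floor))`. The applied transforms are recorded in
#' the dataset provenance.
#'
#' @param data a `labeled_dataset` or a numeric matrix with column names.
#' @param spec a [transform_spec()].
#' @return the transformed object of the same type.
#' @export
apply_transform <- function(data, spec = transform_spec()) {
  if (!inherits(spec, "transform_spec"))
    stop("`spec` must come from transform_spec()")
  is_ds <- inherits(data, "labeled_dataset")
  mat <- if (is_ds) data$matrix else as.matrix(data)
  channels <- colnames(mat)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(ncol(mat)))

  kind <- spec$kind
  if (length(kind) == 1L && is.null(names(kind))) {
    kind <- setNames(rep(kind, ncol(mat)), channels)
  } else {
    missing <- setdiff(names(kind), channels)
    if (length(missing))
      stop("transform names channels absent from the data: ",
           paste(missing, collapse = ", "))
    full <- setNames(rep("none", ncol(mat)), channels)
    full[names(kind)] <- kind
    kind <- full
  }

  for (ch in channels) {
    mat[, ch] <- switch(kind[[ch]],
      asinh = asinh(mat[, ch] / spec$cofactor),
      log10 = log10(pmax(mat[, ch], spec$log_floor)),
      none = mat[, ch])
  }

  desc <- sprintf("%s(cofactor=%g)", kind, spec$cofactor)
  desc[kind != "asinh"] <- kind[kind != "asinh"]
  applied <- paste0(channels, ":", desc)

  if (is_ds) {
    data$matrix <- mat
    data$transforms_applied <- c(data$transforms_applied, applied)
    data
  } else {
    attr(mat, "transforms_applied") <- applied
    mat
  }
}

#' Read event-level data from delimited files (or FCS)
#'
#' Reads one or more CSV/TSV event tables (header row mandatory, `.`
#' decimal) into a single `labeled_dataset`; multiple files with identical
#' channel sets are concatenated, with every source recorded in the
#' provenance. A basic FCS 3.0/3.1 list-mode reader (float/double data)
#' is available via `format = "fcs"`.
#'
#' @param path one or more file paths.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"fcs"`.
#' @param channels optional character vector selecting channels; an error
#'   listing the available channels is raised for missing ones.
#' @param labels_column optional name of a class-label column.
#' @return a `labeled_dataset`.
#' @export
read_events <- function(path, format = c("auto", "csv", "tsv", "fcs"),
                        channels = NULL, labels_column = NULL) {
  format <- match.arg(format)
  parts <- lapply(path, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    fmt <- format
    if (fmt == "auto") {
      fmt <- switch(tolower(tools::file_ext(p)),
                    csv = "csv", tsv = "tsv", txt = "tsv", fcs = "fcs",
                    stop("cannot infer format of '", p,
                         "'; pass `format` explicitly"))
    }
    if (fmt == "fcs") {
      list(table = NULL, fcs = read_fcs(p))
    } else {
      dt <- tryCatch(
        data.table::fread(p, sep = if (fmt == "csv") "," else "\t",
                          header = TRUE, data.table = FALSE),
        error = function(e) stop(sprintf("malformed %s file '%s': %s",
                                         fmt, p, conditionMessage(e))))
      list(table = dt, fcs = NULL)
    }
  })

  tabs <- lapply(seq_along(parts), function(i) {
    if (!is.null(parts[[i]]$fcs)) as.data.frame(parts[[i]]$fcs$matrix)
    else parts[[i]]$table
  })
  cols <- lapply(tabs, colnames)
  if (length(unique(vapply(cols, paste, character(1), collapse = "\r"))) != 1L)
    stop("files cannot be concatenated: channel sets differ")
  tab <- do.call(rbind, tabs)

  labels <- NULL
  if (!is.null(labels_column)) {
    if (!labels_column %in% colnames(tab))
      stop(sprintf("label column '%s' not found; available columns: %s",
                   labels_column, paste(colnames(tab), collapse = ", ")))
    labels <- factor(tab[[labels_column]])
    tab <- tab[, setdiff(colnames(tab), labels_column), drop = FALSE]
  }
  if (is.null(channels)) {
    channels <- colnames(tab)
  } else {
    missing <- setdiff(channels, colnames(tab))
    if (length(missing))
      stop(sprintf("channel(s) %s not found; available channels: %s",
                   paste(missing, collapse = ", "),
                   paste(colnames(tab), collapse = ", ")))
  }
  mat <- as.matrix(tab[, channels, drop = FALSE])
  if (!is.numeric(mat)) stop("selected channels contain non-numeric data")

  structure(
    list(matrix = mat, channels = channels, labels = labels,
         transforms_applied = character(0),
         provenance = list(source = path, n_events = nrow(mat)),
         seed = NA_integer_),
    class = "labeled_dataset")
}

#' Write a labeled dataset as CSV
#'
#' The event matrix plus, when present, a `label` column; the round-trip
#' through [read_events()] restores the matrix bit-exactly.
#'
#' @param dataset a `labeled_dataset`.
#' @param path output path.
#' @export
write_events <- function(dataset, path) {
  if (!inherits(dataset, "labeled_dataset"))
    stop("`dataset` must be a labeled_dataset")
  df <- as.data.frame(apply(dataset$matrix, 2L, sprintf, fmt = "%.17g"))
  if (!is.null(dataset$labels)) df$label <- as.character(dataset$labels)
  data.table::fwrite(df, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Write an embedding with its trace and run summary
#'
#' Writes a tidy coordinate table (`event`, `tsne1`, `tsne2`, `label`) to
#' `path`, the full per-iteration KLD/KLDRC trace to `<path>.trace.tsv`,
#' and a machine-readable run summary (config echo, EE stop, endpoint
#' KLD) to `<path>.summary.json`. Coordinates are written to full double
#' precision.
#'
#' @param result an `optsne_result`.
#' @param labels optional per-event class labels.
#' @param path output path for the coordinate table.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(result, labels = NULL, path) {
  if (!inherits(result, "optsne_result"))
    stop("`result` must be an optsne_result")
  n <- nrow(result$coords)
  df <- data.frame(event = seq_len(n),
                   tsne1 = sprintf("%.17g", result$coords[, 1]),
                   tsne2 = sprintf("%.17g", result$coords[, 2]))
  if (!is.null(labels)) {
    if (length(labels) != n) stop("`labels` length must match the embedding")
    df$label <- as.character(labels)
  }
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)

  trace <- data.frame(iteration = seq_len(result$total_iterations),
                      phase = result$phase_trace,
                      kld = sprintf("%.17g", result$kld_trace),
                      kldrc = sprintf("%.17g", result$kldrc_trace))
  data.table::fwrite(trace, paste0(path, ".trace.tsv"), sep = "\t",
                     quote = FALSE)

  cfg <- result$config
  cfg$k_neighbors <- if (is.null(cfg$k_neighbors)) NA else cfg$k_neighbors
  summary <- list(config = unclass(cfg),
                  eta = result$eta,
                  ls_flag = result$ls_flag,
                  ee_stop_iteration = result$ee_stop_iteration,
                  kldrc_peak_iteration = result$kldrc_peak_iteration,
                  total_iterations = result$total_iterations,
                  endpoint_kld = result$endpoint_kld,
                  seed = result$seed,
                  n = n)
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
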