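#' Minimal FCS 3.0/3.1 reader
#'
#' Reads list-mode FCS containers with floating-point data
#' (`$DATATYPE` `F` or `D`), the common on-disk form of compensated and
#' pre-processed cytometry exports. Parameter names are taken from the
#' `$PnN` keywords, with `$PnS` stain names kept as an attribute. This is
#' a deliberately small reader covering the standard single-dataset
#' layout; integer data types, analysis segments and multi-dataset files
#' are out of scope.
#'
#' @param path path to an FCS file.
#' @return list with `matrix` (event x parameter, `$PnN` column names),
#'   `keywords` (the TEXT segment as a named character vector), and
#'   `stain_names` (`$PnS`, `NA` where absent).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))

  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop(sprintf("'%s' is not an FCS 3.0/3.1 file (header '%s')",
                 path, version))
  offsets <- suppressWarnings(as.numeric(c(
    substr(header, 11L, 18L), substr(header, 19L, 26L),
    substr(header, 27L, 34L), substr(header, 35L, 42L))))
  if (any(is.na(offsets[1:2])))
    stop("malformed FCS header: unreadable TEXT segment offsets")
  text_start <- offsets[1]; text_end <- offsets[2]

  seek(con, text_start)
  text <- rawToChar(readBin(con, "raw", text_end - text_start + 1L))
  delim <- substr(text, 1L, 1L)
  fields <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1]]
  if (length(fields) < 2L) stop("malformed FCS TEXT segment")
  if (length(fields) %% 2L == 1L) fields <- fields[-length(fields)]
  kw <- setNames(fields[seq(2L, length(fields), 2L)],
                 toupper(trimws(fields[seq(1L, length(fields), 2L)])))

  need <- c("$DATATYPE", "$MODE", "$PAR", "$TOT", "$BYTEORD")
  if (!all(need %in% names(kw)))
    stop("FCS TEXT segment is missing required keywords: ",
         paste(setdiff(need, names(kw)), collapse = ", "))
  if (kw[["$MODE"]] != "L") stop("only list-mode ($MODE L) FCS is supported")
  type <- kw[["$DATATYPE"]]
  if (!type %in% c("F", "D"))
    stop(sprintf("unsupported $DATATYPE '%s' (only F/D floating point)", type))
  endian <- switch(kw[["$BYTEORD"]],
                   "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop("unsupported $BYTEORD: ", kw[["$BYTEORD"]]))

  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  data_start <- offsets[3]
  if (is.na(data_start) || data_start == 0)
    data_start <- as.numeric(kw[["$BEGINDATA"]])
  if (!is.finite(data_start) || data_start <= 0)
    stop("cannot locate the FCS DATA segment")

  size <- if (type == "F") 4L else 8L
  seek(con, data_start)
  vals <- readBin(con, "numeric", n = npar * ntot, size = size,
                  endian = endian)
  if (length(vals) < npar * ntot)
    stop("FCS DATA segment shorter than $PAR * $TOT values")

  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  pnn <- vapply(seq_len(npar), function(i) {
    key <- sprintf("$P%dN", i)
    if (key %in% names(kw)) kw[[key]] else sprintf("P%d", i)
  }, character(1))
  pns <- vapply(seq_len(npar), function(i) {
    key <- sprintf("$P%dS", i)
    if (key %in% names(kw)) kw[[key]] else NA_character_
  }, character(1))
  colnames(mat) <- pnn

  list(matrix = mat, keywords = kw, stain_names = pns)
}
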