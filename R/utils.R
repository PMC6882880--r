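# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All user-facing stochastic entry points
# take an explicit seed and go through this, so package calls never perturb
# the session RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

as_numeric_matrix <- function(x, arg = "data") {
  if (inherits(x, "labeled_dataset")) x <- x$matrix
  x <- as.matrix(x)
  if (!is.numeric(x)) stop(sprintf("`%s` must be a numeric matrix", arg))
  x
}

check_finite <- function(x, arg = "data") {
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains NaN/Inf or missing values", arg))
  invisible(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
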