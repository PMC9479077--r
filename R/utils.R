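# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the global
# state afterwards. `seed = NULL` uses (and advances) the global stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "flimredox_parameter_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must be supplied.", name),
          class = "flimredox_parameter_error")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "flimredox_parameter_error")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must lie in [%s, %s] (got %s).",
                  name, format(lower), format(upper), format(x)),
          class = "flimredox_parameter_error")
  }
  invisible(x)
}

# complementary error function, numerically stable on the log scale
log_erfc <- function(x) {
  log(2) + pnorm(-x * sqrt(2), log.p = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
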