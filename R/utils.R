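# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed errors so callers can distinguish argument misuse from data problems.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hypervine_error", "error")))
}

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package go through
# this; nothing touches the global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

logistic <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Division returning NA (not Inf/NaN) where the denominator is exactly zero.
safe_div <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Deterministic CSV writer: fixed field order, no quoting surprises, full
# double precision via R's default 15-significant-digit character conversion.
write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA",
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
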