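# Internal helpers: local RNG scoping and input checks.

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream. All randomized steps in the package go through this, so results are
# reproducible from the documented seeds alone.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_f <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)) || x < min) {
    stop_f("`%s` must be a single %snumber >= %s", name,
           if (finite) "finite " else "", format(min))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) stop_f("`%s` must be a data.frame", name)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_f("`%s` is missing column(s): %s", name, paste(missing, collapse = ", "))
  }
  invisible(df)
}
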