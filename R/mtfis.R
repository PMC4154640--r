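#' Assemble per-condition fits into a multi-treatment model (mtFIS)
#'
#' An mtFIS holds one pair of rule consequents per treatment condition behind
#' a shared fixed premise, for `2 * n_conditions` rules in total and no new
#' free parameters. A naive condition switch — an exact 0/1 indicator on the
#' active condition — gates the rule blocks, so evaluation under condition
#' `c` reproduces the condition-`c` gFIS to machine precision. The indicator
#' form is semantically equivalent to encoding the switch with Boolean-shaped
#' trapezoidal membership functions, and numerically exact. Only one
#' condition can be active per evaluation (single-drug treatments).
#'
#' @param per_condition named list mapping condition label to a [gfis()] or
#'   [fit_gfis()] result. All component models must share the same number of
#'   inputs and the same premise parameters.
#' @return an object of class `"mtfis"`.
#' @examples
#' g1 <- gfis(rbind(c(0, 0), c(0, 1)))
#' g2 <- gfis(rbind(c(0, 1), c(0, 0)))
#' m <- assemble_mtfis(list(control = g1, drug = g2))
#' evaluate_mtfis(m, 0.3, "drug")
#' @export
assemble_mtfis <- function(per_condition) {
  if (!is.list(per_condition) || length(per_condition) < 1L ||
      is.null(names(per_condition)) || any(!nzchar(names(per_condition)))) {
    stop_f("`per_condition` must be a non-empty named list of models")
  }
  models <- lapply(per_condition, function(m) {
    if (inherits(m, "gfis_fit")) m <- m$model
    if (!inherits(m, "gfis")) stop_f("every element must be a gfis or gfis_fit")
    m
  })
  n <- unique(vapply(models, function(m) m$n_inputs, integer(1)))
  if (length(n) != 1L) {
    stop_f("all per-condition models must share n_inputs (got: %s)",
           paste(sort(n), collapse = ", "))
  }
  first <- models[[1L]]
  for (m in models[-1L]) {
    if (!isTRUE(all.equal(m$centers, first$centers)) ||
        !isTRUE(all.equal(m$widths, first$widths))) {
      stop_f("all per-condition models must share the same premise parameters")
    }
  }
  structure(
    list(
      conditions = names(models),
      n_inputs = n,
      n_rules = 2L * length(models),
      centers = first$centers,
      widths = first$widths,
      consequents = lapply(models, function(m) m$consequents)
    ),
    class = "mtfis"
  )
}

# The gFIS encoded for one condition (the switch selects this block exactly).
condition_gfis <- function(m, condition) {
  stopifnot(inherits(m, "mtfis"))
  if (length(condition) != 1L || !condition %in% m$conditions) {
    stop_f("unknown condition '%s'; valid conditions: %s",
           paste(condition, collapse = ","),
           paste(m$conditions, collapse = ", "))
  }
  gfis(m$consequents[[condition]], centers = m$centers, widths = m$widths)
}

#' Evaluate an mtFIS under one treatment condition
#'
#' The condition switch zeroes the firing strength of every rule block except
#' the active condition's, so the result equals [evaluate_gfis()] on the
#' source per-condition model exactly.
#'
#' @param m an [assemble_mtfis()] object.
#' @param x input vector of length `n_inputs`, or a matrix with one row per
#'   observation.
#' @param condition the active condition label; must be one of
#'   `m$conditions` (exactly one condition is active per evaluation).
#' @return numeric vector of model outputs.
#' @export
evaluate_mtfis <- function(m, x, condition) {
  evaluate_gfis(condition_gfis(m, condition), x)
}

#' @export
predict.mtfis <- function(object, newdata, condition, ...) {
  evaluate_mtfis(object, newdata, condition)
}

#' @export
print.mtfis <- function(x, ...) {
  cat(sprintf("mtFIS: %d input(s), %d conditions, %d rules\n",
              x$n_inputs, length(x$conditions), x$n_rules))
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}
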