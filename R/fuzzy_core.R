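#' Gaussian membership function
#'
#' Degree of membership of `x` in a Gaussian fuzzy set,
#' `exp(-(x - center)^2 / (2 * width^2))`. The degree is 1 at the center and
#' strictly positive on the whole real line, so rule firing strengths never
#' vanish simultaneously.
#'
#' @param x numeric vector of (finite) input values.
#' @param center center of the fuzzy set (membership 1 there).
#' @param width width (standard-deviation-like) parameter, > 0.
#' @return numeric vector of membership degrees in (0, 1].
#' @examples
#' gauss_membership(0, center = 0, width = 0.4247) # 1
#' gauss_membership(0.4247, center = 0, width = 0.4247) # exp(-0.5)
#' @export
gauss_membership <- function(x, center, width) {
  check_number(center, "center")
  check_number(width, "width")
  if (width <= 0) stop_f("`width` must be > 0 (got %g)", width)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_f("`x` must be finite numeric")
  }
  exp(-(x - center)^2 / (2 * width^2))
}

# Fixed premise width: the conventional default width for Gaussian input
# membership functions on [0, 1]-scaled data.
GFIS_DEFAULT_WIDTH <- 0.4247

#' Construct a parameter-reduced first-order Takagi-Sugeno model (gFIS)
#'
#' A gFIS has exactly two rules regardless of the number of inputs: rule 1
#' combines the *low* fuzzy set of every input (Gaussian centered at 0) and
#' rule 2 the *high* set of every input (centered at 1). Premise parameters
#' are fixed (centers 0/1, width 0.4247 by default), so the free parameters
#' are the two linear rule consequents: `2 * (n_inputs + 1)` in total.
#' Consequent coefficients may be negative, which lets a single rule pair
#' encode inhibition as well as activation.
#'
#' @param consequents 2 x (n_inputs + 1) numeric matrix. Row 1 is the low
#'   rule, row 2 the high rule; the first `n_inputs` columns are the input
#'   coefficients (p) and the last column the intercept (q).
#' @param centers optional 2 x n_inputs matrix of premise centers
#'   (row 1 low, row 2 high); defaults to 0 and 1 for every input.
#' @param widths optional 2 x n_inputs matrix of premise widths (> 0);
#'   defaults to `0.4247` everywhere. Only the free-premise model setups of
#'   the sensitivity analysis override these.
#' @return an object of class `"gfis"`.
#' @seealso [evaluate_gfis()], [fit_gfis()], [parameter_budget()]
#' @examples
#' m <- gfis(rbind(c(0, 0), c(0, 1))) # low rule -> 0, high rule -> 1
#' evaluate_gfis(m, c(0, 0.5, 1))
#' @export
gfis <- function(consequents, centers = NULL, widths = NULL) {
  consequents <- as.matrix(consequents)
  if (nrow(consequents) != 2L || ncol(consequents) < 2L) {
    stop_f("`consequents` must be a 2 x (n_inputs + 1) matrix with n_inputs >= 1")
  }
  if (any(!is.finite(consequents))) stop_f("consequent parameters must be finite")
  n <- ncol(consequents) - 1L
  if (is.null(centers)) centers <- rbind(rep(0, n), rep(1, n))
  if (is.null(widths)) widths <- matrix(GFIS_DEFAULT_WIDTH, 2L, n)
  centers <- matrix(as.numeric(centers), 2L, n)
  widths <- matrix(as.numeric(widths), 2L, n)
  if (any(!is.finite(centers)) || any(!is.finite(widths)) || any(widths <= 0)) {
    stop_f("premise centers must be finite and widths finite and > 0")
  }
  structure(
    list(
      n_inputs = n,
      centers = centers,
      widths = widths,
      consequents = consequents
    ),
    class = "gfis"
  )
}

# Coerce an input vector / matrix / data.frame to an n_obs x n_inputs matrix.
as_input_matrix <- function(x, n_inputs) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (n_inputs == 1L) {
      x <- matrix(x, ncol = 1L)
    } else if (length(x) == n_inputs) {
      x <- matrix(x, nrow = 1L)
    } else {
      stop_f("input has length %d but the model expects %d input(s)",
             length(x), n_inputs)
    }
  }
  if (ncol(x) != n_inputs) {
    stop_f("input has %d column(s) but the model expects %d input(s)",
           ncol(x), n_inputs)
  }
  if (any(!is.finite(x))) stop_f("model inputs must be finite")
  storage.mode(x) <- "double"
  x
}

#' Rule firing strengths of a gFIS
#'
#' The firing strength of each rule is the product (t-norm) over inputs of
#' the corresponding Gaussian memberships: rule 1 uses the low set of every
#' input, rule 2 the high set. Both strengths are in (0, 1], so their sum is
#' always positive.
#'
#' @param model a [gfis()] object.
#' @param x input vector of length `n_inputs`, or a matrix/data.frame with
#'   one row per observation.
#' @return an n_obs x 2 matrix with columns `w1` (low rule) and `w2`
#'   (high rule).
#' @export
firing_strengths <- function(model, x) {
  stopifnot(inherits(model, "gfis"))
  X <- as_input_matrix(x, model$n_inputs)
  w <- matrix(NA_real_, nrow(X), 2L, dimnames = list(NULL, c("w1", "w2")))
  for (r in 1:2) {
    z <- sweep(X, 2L, model$centers[r, ], "-")
    z <- sweep(z^2, 2L, 2 * model$widths[r, ]^2, "/")
    w[, r] <- exp(-rowSums(z))
  }
  w
}

#' Evaluate a gFIS
#'
#' First-order Takagi-Sugeno inference: each rule's linear consequent
#' `f_r(x) = sum_j p_rj x_j + q_r` is weighted by the rule's normalized
#' firing strength, `y = (w1 f1 + w2 f2) / (w1 + w2)`. The output is a
#' pointwise convex combination of the two rule polynomials. Inputs are not
#' clipped to [0, 1]: the membership functions are defined on the whole real
#' line and simulated upstream signals may transiently leave the unit
#' interval.
#'
#' @inheritParams firing_strengths
#' @return numeric vector of model outputs, one per observation.
#' @export
evaluate_gfis <- function(model, x) {
  stopifnot(inherits(model, "gfis"))
  X <- as_input_matrix(x, model$n_inputs)
  w <- firing_strengths(model, X)
  n <- model$n_inputs
  f1 <- X %*% model$consequents[1L, seq_len(n)] + model$consequents[1L, n + 1L]
  f2 <- X %*% model$consequents[2L, seq_len(n)] + model$consequents[2L, n + 1L]
  drop((w[, 1L] * f1 + w[, 2L] * f2) / (w[, 1L] + w[, 2L]))
}

#' @export
predict.gfis <- function(object, newdata, ...) {
  evaluate_gfis(object, newdata)
}

#' @export
print.gfis <- function(x, ...) {
  cat(sprintf("gFIS: %d input(s), 2 rules, %d free consequent parameters\n",
              x$n_inputs, 2L * (x$n_inputs + 1L)))
  cat(sprintf("  premise centers: low %s / high %s; widths %s\n",
              paste(format(x$centers[1, ]), collapse = ", "),
              paste(format(x$centers[2, ]), collapse = ", "),
              paste(format(unique(as.vector(x$widths))), collapse = ", ")))
  cons <- x$consequents
  rownames(cons) <- c("low rule", "high rule")
  colnames(cons) <- c(paste0("p", seq_len(x$n_inputs)), "q")
  print(cons)
  invisible(x)
}

#' Parameter accounting for the reduction scheme
#'
#' Counts rules and parameters of a two-fuzzy-sets-per-input first-order
#' Takagi-Sugeno model under the three stages of the parameter-reduction
#' scheme:
#' \describe{
#'   \item{`grid`}{full grid partition: every combination of input sets is a
#'     rule (`2^n` rules); each Gaussian set has 2 premise parameters (`4n`
#'     in total) and each rule a linear consequent with `n + 1` parameters.}
#'   \item{`constrained_rules`}{only rules combining analogous sets (all-low,
#'     all-high) are kept: 2 rules, the same `4n` premise parameters and
#'     `2(n + 1)` consequent parameters.}
#'   \item{`fixed_premise`}{as `constrained_rules`, but premise centers and
#'     widths are fixed constants, leaving only the `2(n + 1)` consequent
#'     parameters free. This is the gFIS.}
#' }
#'
#' @param n_inputs number of regulators feeding the model (>= 1).
#' @param scheme one of `"grid"`, `"constrained_rules"`, `"fixed_premise"`.
#' @return a list with `n_rules`, `n_premise_params`, `n_consequent_params`
#'   and `n_free` (the number of parameters that must be estimated).
#' @examples
#' parameter_budget(2, "grid")$n_free # 20
#' parameter_budget(2, "constrained_rules")$n_free # 14
#' parameter_budget(2, "fixed_premise")$n_free # 6
#' @export
parameter_budget <- function(n_inputs,
                             scheme = c("grid", "constrained_rules", "fixed_premise")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n_inputs) || length(n_inputs) != 1L ||
      n_inputs < 1 || n_inputs != round(n_inputs)) {
    stop_f("`n_inputs` must be an integer >= 1")
  }
  n <- as.integer(n_inputs)
  premise <- 4L * n # 2 fuzzy sets per input x (center, width)
  switch(scheme,
    grid = {
      rules <- 2L^n
      consequent <- rules * (n + 1L)
      list(n_rules = rules, n_premise_params = premise,
           n_consequent_params = consequent, n_free = premise + consequent)
    },
    constrained_rules = {
      consequent <- 2L * (n + 1L)
      list(n_rules = 2L, n_premise_params = premise,
           n_consequent_params = consequent, n_free = premise + consequent)
    },
    fixed_premise = {
      consequent <- 2L * (n + 1L)
      list(n_rules = 2L, n_premise_params = premise,
           n_consequent_params = consequent, n_free = consequent)
    }
  )
}
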