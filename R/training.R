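#' Training set for a single node and condition
#'
#' Bundles the regulator matrix and target vector a gFIS is fitted to. Values
#' are expected on the preprocessed [0, 1] scale.
#'
#' @param X numeric matrix of input values, one row per time point and one
#'   column per regulator (a vector is treated as a single column).
#' @param y numeric target vector, `length(y) == nrow(X)`.
#' @param times optional time stamps (hours) of the rows.
#' @param node,condition optional labels carried along for error messages.
#' @return an object of class `"training_set"`.
#' @export
training_set <- function(X, y, times = NULL, node = NULL, condition = NULL) {
  if (is.null(dim(X))) X <- matrix(as.numeric(X), ncol = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_f("nrow(X) (%d) != length(y) (%d)", nrow(X), length(y))
  if (nrow(X) < 2L) stop_f("a training set needs at least 2 rows")
  if (any(!is.finite(X)) || any(!is.finite(y))) stop_f("training data must be finite")
  structure(
    list(X = X, y = y, times = times, node = node, condition = condition),
    class = "training_set"
  )
}

as_training_set <- function(data) {
  if (inherits(data, "training_set")) return(data)
  if (is.list(data) && all(c("X", "y") %in% names(data))) {
    return(training_set(data$X, data$y, data$times, data$node, data$condition))
  }
  stop_f("`data` must be a training_set (see training_set())")
}

#' Configuration of the penalized training objective
#'
#' @param n_interp number of synthetic points per input axis used to probe
#'   the model between the data points (default 20). For multi-input models
#'   the per-axis grids are combined into a full Cartesian grid.
#' @param n_restarts number of random restarts of the derivative-free
#'   optimizer (default 20).
#' @param seed master seed; restart `i` uses `seed + i - 1`, so restarts are
#'   independent and the whole fit is reproducible.
#' @param init_range range of the uniform distribution initial consequent
#'   parameters are drawn from.
#' @param lower,upper range outside which interpolated model output is
#'   penalized (the measurement scale is [0, 1]).
#' @param maxit maximum iterations per optimizer run.
#' @param grid_range optional 2 x n_inputs matrix (min/max per input) fixing
#'   the span of the interpolation grid. By default the grid spans the
#'   observed range of each input in the training set; resampling analyses
#'   pin it to the full original range so that a bootstrap replicate without
#'   the extreme input values is still required to stay in range across the
#'   measured input domain.
#' @return a list of class `"objective_config"`.
#' @export
objective_config <- function(n_interp = 20L, n_restarts = 20L, seed = 1L,
                             init_range = c(-2, 2), lower = 0, upper = 1,
                             maxit = 1500L, grid_range = NULL) {
  check_number(n_interp, "n_interp", min = 1)
  check_number(n_restarts, "n_restarts", min = 1)
  check_number(seed, "seed")
  stopifnot(length(init_range) == 2L, init_range[1] < init_range[2], lower < upper)
  if (!is.null(grid_range)) {
    grid_range <- as.matrix(grid_range)
    stopifnot(nrow(grid_range) == 2L, all(grid_range[1, ] <= grid_range[2, ]))
  }
  structure(
    list(n_interp = as.integer(n_interp), n_restarts = as.integer(n_restarts),
         seed = as.integer(seed), init_range = as.numeric(init_range),
         lower = lower, upper = upper, maxit = as.integer(maxit),
         grid_range = grid_range),
    class = "objective_config"
  )
}

# ---- model setups -----------------------------------------------------------
#
# fixed_linear     : fixed Gaussian premises, free linear consequents (gFIS);
#                    theta = (p1[1..n], q1, p2[1..n], q2), 2(n+1) parameters.
# adaptive_constant: free premises, constant consequents (zero-order model);
#                    theta = (a[1..n], sa[1..n], b[1..n], sb[1..n], q1, q2),
#                    4n + 2 parameters.
# adaptive_linear  : free premises, free linear consequents;
#                    theta = (a, sa, b, sb, p1, q1, p2, q2), 4n + 2(n+1).

MODEL_SETUPS <- c("fixed_linear", "adaptive_constant", "adaptive_linear")

#' Number of free parameters of a model setup
#'
#' @param n_inputs number of regulators (>= 1).
#' @param setup one of `"fixed_linear"` (the gFIS), `"adaptive_constant"`
#'   (free premises, constant consequents) or `"adaptive_linear"` (free
#'   premises, linear consequents).
#' @return integer parameter count: `2(n+1)`, `4n + 2` and `4n + 2(n+1)`
#'   respectively.
#' @export
setup_free_params <- function(n_inputs, setup = MODEL_SETUPS) {
  setup <- match.arg(setup)
  n <- as.integer(n_inputs)
  if (n < 1L) stop_f("`n_inputs` must be >= 1")
  switch(setup,
    fixed_linear = 2L * (n + 1L),
    adaptive_constant = 4L * n + 2L,
    adaptive_linear = 4L * n + 2L * (n + 1L)
  )
}

# Build a gfis object from a flat parameter vector under a given setup.
# Premise widths are passed through abs() with a small floor so any real
# vector yields a valid model during unconstrained optimization.
gfis_from_theta <- function(theta, n_inputs, setup = "fixed_linear") {
  n <- as.integer(n_inputs)
  k <- setup_free_params(n, setup)
  if (length(theta) != k) {
    stop_f("theta has length %d but setup '%s' with %d input(s) needs %d",
           length(theta), setup, n, k)
  }
  if (setup == "fixed_linear") {
    cons <- rbind(theta[1:(n + 1)], theta[(n + 2):(2 * n + 2)])
    return(gfis(cons))
  }
  a <- theta[seq_len(n)]
  sa <- theta[n + seq_len(n)]
  b <- theta[2 * n + seq_len(n)]
  sb <- theta[3 * n + seq_len(n)]
  rest <- theta[-seq_len(4 * n)]
  cons <- if (setup == "adaptive_constant") {
    rbind(c(rep(0, n), rest[1]), c(rep(0, n), rest[2]))
  } else {
    rbind(rest[1:(n + 1)], rest[(n + 2):(2 * n + 2)])
  }
  gfis(cons,
       centers = rbind(a, b),
       widths = rbind(pmax(abs(sa), 1e-3), pmax(abs(sb), 1e-3)))
}

gfis_to_theta <- function(model) {
  n <- model$n_inputs
  c(model$consequents[1L, ], model$consequents[2L, ])
}

# ---- objective --------------------------------------------------------------

#' Root-mean-square error of a model on a training set
#'
#' @param model a [gfis()] object.
#' @param data a [training_set()].
#' @return `sqrt(mean((yhat - y)^2))` over the training rows.
#' @export
gfis_rmse <- function(model, data) {
  data <- as_training_set(data)
  yhat <- evaluate_gfis(model, data$X)
  sqrt(mean((yhat - data$y)^2))
}

# Cartesian grid of n_interp equidistant points per input axis, spanning the
# observed range of each input (or cfg$grid_range when pinned). Single-input
# models probe n_interp points between the data points; with n inputs the
# grid has n_interp^n points.
interpolation_grid <- function(X, n_interp, grid_range = NULL) {
  axes <- lapply(seq_len(ncol(X)), function(j) {
    r <- if (is.null(grid_range)) range(X[, j]) else grid_range[, j]
    seq(r[1], r[2], length.out = n_interp)
  })
  as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

#' Out-of-range interpolation penalty
#'
#' The fitted model is probed on a synthetic grid between the data points;
#' every simulated value above 1 (positive offset) or below 0 (negative
#' offset) contributes its squared distance to the admissible range. The
#' penalty is the root mean square of these offsets over the grid, added to
#' the training RMSE so that fits which are accurate at the data points but
#' wild between them are rejected.
#'
#' @param model a [gfis()] object.
#' @param data the [training_set()] whose input ranges define the grid.
#' @param cfg an [objective_config()]; `cfg$n_interp` points per axis.
#' @return non-negative penalty, 0 when the model stays in range on the grid.
#' @export
interpolation_penalty <- function(model, data, cfg = objective_config()) {
  data <- as_training_set(data)
  grid <- interpolation_grid(data$X, cfg$n_interp, cfg$grid_range)
  yhat <- evaluate_gfis(model, grid)
  pos <- pmax(yhat - cfg$upper, 0)
  neg <- pmax(cfg$lower - yhat, 0)
  sqrt(mean(pos^2 + neg^2))
}

#' Penalized training objective
#'
#' `objective = RMSE + interpolation penalty` for the model built from the
#' flat parameter vector `theta` under the given setup.
#'
#' @param theta flat parameter vector (see [setup_free_params()] for the
#'   required length).
#' @param data a [training_set()].
#' @param cfg an [objective_config()].
#' @param setup model setup, see [setup_free_params()].
#' @return the scalar objective value.
#' @export
gfis_objective <- function(theta, data, cfg = objective_config(),
                           setup = "fixed_linear") {
  data <- as_training_set(data)
  model <- gfis_from_theta(theta, ncol(data$X), setup)
  gfis_rmse(model, data) + interpolation_penalty(model, data, cfg)
}

# Fast objective closure. For the fixed-premise gFIS the normalized firing
# strengths do not depend on theta, so model output is linear in theta and
# both RMSE and penalty reduce to matrix products with precomputed designs.
make_objective <- function(data, cfg, setup) {
  X <- data$X
  y <- data$y
  n <- ncol(X)
  grid <- interpolation_grid(X, cfg$n_interp, cfg$grid_range)
  if (setup == "fixed_linear") {
    base <- gfis(matrix(0, 2L, n + 1L))
    design <- function(M) {
      w <- firing_strengths(base, M)
      g <- w / rowSums(w)
      cbind(g[, 1L] * cbind(M, 1), g[, 2L] * cbind(M, 1))
    }
    A <- design(X)
    G <- design(grid)
    function(theta) {
      yhat <- A %*% theta
      yg <- G %*% theta
      sqrt(mean((yhat - y)^2)) +
        sqrt(mean(pmax(yg - cfg$upper, 0)^2 + pmax(cfg$lower - yg, 0)^2))
    }
  } else {
    # free-premise setups: memberships depend on theta, computed inline
    tX <- t(X)
    tG <- t(grid)
    zero_p <- setup == "adaptive_constant"
    function(theta) {
      a <- theta[seq_len(n)]
      sa <- pmax(abs(theta[n + seq_len(n)]), 1e-3)
      b <- theta[2 * n + seq_len(n)]
      sb <- pmax(abs(theta[3 * n + seq_len(n)]), 1e-3)
      rest <- theta[-seq_len(4 * n)]
      p1 <- if (zero_p) numeric(n) else rest[seq_len(n)]
      q1 <- if (zero_p) rest[1L] else rest[n + 1L]
      p2 <- if (zero_p) numeric(n) else rest[n + 1L + seq_len(n)]
      q2 <- if (zero_p) rest[2L] else rest[2L * n + 2L]
      eval_at <- function(tM, M) {
        w1 <- exp(-colSums((tM - a)^2 / (2 * sa^2)))
        w2 <- exp(-colSums((tM - b)^2 / (2 * sb^2)))
        f1 <- M %*% p1 + q1
        f2 <- M %*% p2 + q2
        (w1 * f1 + w2 * f2) / (w1 + w2)
      }
      yhat <- eval_at(tX, X)
      yg <- eval_at(tG, grid)
      sqrt(mean((yhat - y)^2)) +
        sqrt(mean(pmax(yg - cfg$upper, 0)^2 + pmax(cfg$lower - yg, 0)^2))
    }
  }
}

# Warm start: least-squares consequents under the fixed default premises
# (closed form, since output is linear in the consequents there), premise
# parameters at their defaults for the free-premise setups. Used as the first
# restart of every fit; random restarts guard against the penalty term and,
# for the free-premise setups, against the warm start's basin.
warm_theta <- function(data, setup) {
  X <- data$X
  n <- ncol(X)
  base <- gfis(matrix(0, 2L, n + 1L))
  w <- firing_strengths(base, X)
  g <- w / rowSums(w)
  A <- if (setup == "adaptive_constant") {
    cbind(g[, 1L], g[, 2L])
  } else {
    cbind(g[, 1L] * cbind(X, 1), g[, 2L] * cbind(X, 1))
  }
  cons <- tryCatch(stats::lm.fit(A, data$y)$coefficients,
                   error = function(e) rep(0, ncol(A)))
  cons[is.na(cons)] <- 0
  if (setup == "fixed_linear") return(unname(cons))
  premise <- c(rep(0, n), rep(GFIS_DEFAULT_WIDTH, n),
               rep(1, n), rep(GFIS_DEFAULT_WIDTH, n))
  unname(c(premise, cons))
}

random_theta <- function(n, setup, init_range) {
  k_cons <- if (setup == "adaptive_constant") 2L else 2L * (n + 1L)
  cons <- runif(k_cons, init_range[1], init_range[2])
  if (setup == "fixed_linear") return(cons)
  # premise inits: low centers near 0, high centers near 1, moderate widths
  a <- runif(n, -0.2, 0.3)
  sa <- runif(n, 0.2, 0.8)
  b <- runif(n, 0.7, 1.2)
  sb <- runif(n, 0.2, 0.8)
  c(a, sa, b, sb, cons)
}

#' Fit a model to a training set
#'
#' Minimizes the penalized RMSE objective ([gfis_objective()]) with
#' multi-start Nelder-Mead. The first restart is a deterministic warm start
#' (closed-form least-squares consequents under the default premises); the
#' remaining `cfg$n_restarts - 1` runs start from uniformly randomized
#' parameter vectors. The restart with the lowest objective wins (ties broken
#' by lowest restart index). Restart `i >= 2` seeds its initial draw with
#' `cfg$seed + i - 1`, so results are reproducible and adding restarts can
#' only improve the selected objective.
#'
#' @param data a [training_set()].
#' @param cfg an [objective_config()].
#' @param setup model setup, see [setup_free_params()]; the default
#'   `"fixed_linear"` is the gFIS.
#' @return an object of class `"gfis_fit"` with elements `model` (the fitted
#'   [gfis()]), `theta`, `objective`, `rmse`, `penalty`, `restart` (index of
#'   the winning restart), `setup` and `n_obs`.
#' @export
fit_gfis <- function(data, cfg = objective_config(), setup = MODEL_SETUPS) {
  setup <- match.arg(setup)
  data <- as_training_set(data)
  n <- ncol(data$X)
  k <- setup_free_params(n, setup)
  if (nrow(data$X) <= k) {
    warn_f("training set for %s has %d rows but the %s setup has %d free parameters",
           if (is.null(data$node)) "model" else data$node, nrow(data$X), setup, k)
  }
  fn <- make_objective(data, cfg, setup)
  best <- NULL
  failures <- character(0)
  for (i in seq_len(cfg$n_restarts)) {
    theta0 <- if (i == 1L) {
      warm_theta(data, setup)
    } else {
      with_local_seed(cfg$seed + i - 1L, random_theta(n, setup, cfg$init_range))
    }
    res <- tryCatch(
      optim(theta0, fn, method = "Nelder-Mead",
            control = list(maxit = cfg$maxit, reltol = 1e-10)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("restart %d: %s", i, conditionMessage(res)))
      next
    }
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$restart <- i
    }
  }
  if (is.null(best)) {
    stop_f("all %d restarts failed%s:\n%s",
           cfg$n_restarts,
           if (is.null(data$node)) "" else paste0(" for node ", data$node),
           paste(failures, collapse = "\n"))
  }
  model <- gfis_from_theta(best$par, n, setup)
  rmse <- gfis_rmse(model, data)
  penalty <- interpolation_penalty(model, data, cfg)
  structure(
    list(model = model, theta = best$par, setup = setup,
         objective = rmse + penalty, rmse = rmse, penalty = penalty,
         restart = best$restart, n_obs = nrow(data$X),
         node = data$node, condition = data$condition),
    class = "gfis_fit"
  )
}

#' @export
print.gfis_fit <- function(x, ...) {
  cat(sprintf("gFIS fit (%s)%s: objective %.6g = RMSE %.6g + penalty %.6g (restart %d)\n",
              x$setup,
              if (is.null(x$node)) "" else sprintf(" [%s/%s]", x$node, x$condition),
              x$objective, x$rmse, x$penalty, x$restart))
  print(x$model)
  invisible(x)
}

#' @export
predict.gfis_fit <- function(object, newdata, ...) {
  evaluate_gfis(object$model, newdata)
}
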