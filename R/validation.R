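#' Data-derived (bootstrap) sensitivity analysis
#'
#' Rather than perturbing fitted parameters directly, the training data are
#' resampled: `B` datasets of the original size are drawn row-wise (input,
#' target pairs jointly) with replacement, each is fitted under the requested
#' model setup, and every bootstrapped model is simulated at the *original*
#' data points. The standard deviation of those simulations at each data
#' point, averaged over points (`mean_sigma`), measures how flexibly the
#' setup adapts to changes in the training data; the RMSE of each
#' bootstrapped model against the original data and its spread measure
#' accuracy and its stability.
#'
#' @param data a [training_set()].
#' @param setup model setup, see [setup_free_params()].
#' @param B number of bootstrap resamples (default 100, must be >= 2).
#' @param seed seed for the resampling draws; resample `b` uses
#'   `seed + b`, fits use seeds derived from `cfg$seed` plus the same offset.
#' @param cfg an [objective_config()] used for every fit.
#' @return a list of class `"bootstrap_report"` with `setup`, `B`,
#'   `n_failed`, `predictions` (B x n matrix of simulations at the original
#'   points, failed resamples as `NA` rows), `sigma` (per-point standard
#'   deviation), `mean_sigma`, `boot_rmse`, `error_deviation`
#'   (`sd(boot_rmse)`) and `reference_error` (RMSE of the model fitted to the
#'   full original data).
#' @export
bootstrap_sensitivity <- function(data, setup = MODEL_SETUPS, B = 100L,
                                  seed = 1L, cfg = objective_config()) {
  setup <- match.arg(setup)
  data <- as_training_set(data)
  check_number(B, "B", min = 2)
  B <- as.integer(B)
  n <- nrow(data$X)

  # resampled fits must stay in range across the full measured input domain,
  # not just the resample's span, so pin the interpolation grid to it
  if (is.null(cfg$grid_range)) {
    cfg$grid_range <- apply(data$X, 2L, range)
  }
  ref_fit <- fit_gfis(data, cfg, setup = setup)
  preds <- matrix(NA_real_, B, n)
  boot_rmse <- rep(NA_real_, B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    rows <- with_local_seed(seed + b, sample.int(n, n, replace = TRUE))
    boot_cfg <- cfg
    boot_cfg$seed <- cfg$seed + 1000L * b
    fit <- tryCatch(
      suppressWarnings(
        fit_gfis(training_set(data$X[rows, , drop = FALSE], data$y[rows]),
                 boot_cfg, setup = setup)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    preds[b, ] <- evaluate_gfis(fit$model, data$X)
    boot_rmse[b] <- sqrt(mean((preds[b, ] - data$y)^2))
  }
  if (n_failed > 0.2 * B) {
    stop_f("%d of %d bootstrap fits failed (> 20%%)", n_failed, B)
  }
  sigma <- apply(preds, 2L, sd, na.rm = TRUE)
  structure(
    list(setup = setup, B = B, n_failed = n_failed, predictions = preds,
         sigma = sigma, mean_sigma = mean(sigma),
         boot_rmse = boot_rmse,
         error_deviation = sd(boot_rmse, na.rm = TRUE),
         reference_error = ref_fit$rmse,
         reference_fit = ref_fit),
    class = "bootstrap_report"
  )
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf(
    "bootstrap sensitivity (%s): B = %d (%d failed)\n  mean_sigma = %.4g, reference RMSE = %.4g, error deviation = %.4g\n",
    x$setup, x$B, x$n_failed, x$mean_sigma, x$reference_error, x$error_deviation))
  invisible(x)
}

#' Leave-one-out cross-validation of a gFIS
#'
#' Each data pair is left out in turn; a gFIS is fitted to the remaining
#' pairs and predicts the excluded point from its input value. A reference
#' model fitted to the full dataset predicts every observed input. The
#' Pearson correlation between the test-prediction vector and the reference
#' predictions quantifies over-fitting: a high correlation means the patterns
#' the reference model found persist when each point is held out.
#'
#' @param data a [training_set()] with at least 3 rows.
#' @param cfg an [objective_config()]; fold `k` fits with seed
#'   `cfg$seed + 1000 * k`.
#' @return a list of class `"crossval_report"` with `test_predictions` (one
#'   per left-out row), `reference_predictions`, `observed` and `correlation`.
#' @export
loo_crossval <- function(data, cfg = objective_config()) {
  data <- as_training_set(data)
  n <- nrow(data$X)
  if (n < 3L) stop_f("leave-one-out cross-validation needs at least 3 rows")
  ref_fit <- fit_gfis(data, cfg)
  ref_pred <- evaluate_gfis(ref_fit$model, data$X)
  test_pred <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + 1000L * k
    fit <- tryCatch(
      suppressWarnings(
        fit_gfis(training_set(data$X[-k, , drop = FALSE], data$y[-k]), fold_cfg)
      ),
      error = function(e) {
        stop_f("cross-validation fold %d failed: %s", k, conditionMessage(e))
      }
    )
    test_pred[k] <- evaluate_gfis(fit$model, data$X[k, , drop = FALSE])
  }
  structure(
    list(test_predictions = test_pred,
         reference_predictions = ref_pred,
         observed = data$y,
         correlation = cor(test_pred, ref_pred),
         reference_fit = ref_fit),
    class = "crossval_report"
  )
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("leave-one-out cross-validation: %d folds, R = %.3f\n",
              length(x$test_predictions), x$correlation))
  invisible(x)
}
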