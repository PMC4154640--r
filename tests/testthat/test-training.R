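test_that("training RMSE matches hand and oracle computations", {
  ident <- gfis(rbind(c(1, 0), c(1, 0)))
  x <- seq(0, 1, length.out = 5)
  expect_equal(gfis_rmse(ident, training_set(x, x)), 0)
  # constant 0.5 model vs alternating targets
  const <- gfis(rbind(c(0, 0.5), c(0, 0.5)))
  expect_equal(gfis_rmse(const, training_set(c(0.2, 0.8), c(0, 1))), 0.5)
  set.seed(21)
  m <- random_gfis(2)
  X <- matrix(runif(14), 7, 2)
  y <- runif(7)
  yhat <- evaluate_gfis(m, X)
  expect_equal(gfis_rmse(m, training_set(X, y)), sqrt(sum((yhat - y)^2) / 7))
})

test_that("interpolation penalty measures out-of-range excursions on the grid", {
  cfg <- objective_config()
  x <- seq(0, 1, length.out = 6)
  ts <- training_set(x, x)
  inrange <- gfis(rbind(c(1, 0), c(1, 0)))
  expect_equal(interpolation_penalty(inrange, ts, cfg), 0)
  # constant output 2: every grid point offsets by 1
  high <- gfis(rbind(c(0, 2), c(0, 2)))
  expect_equal(interpolation_penalty(high, ts, cfg), 1)
  # arbitrary model vs a direct recomputation over the same grid
  set.seed(5)
  m <- random_gfis(1)
  grid <- seq(min(x), max(x), length.out = cfg$n_interp)
  yg <- evaluate_gfis(m, grid)
  expect_equal(interpolation_penalty(m, ts, cfg),
               sqrt(mean(pmax(yg - 1, 0)^2 + pmax(-yg, 0)^2)))
})

test_that("objective is RMSE plus penalty and never below RMSE", {
  cfg <- objective_config()
  x <- seq(0, 1, length.out = 8)
  ts <- training_set(x, x)
  theta <- c(1, 0, 1, 0) # identity in both rules: penalty-free
  expect_equal(gfis_objective(theta, ts, cfg), gfis_rmse(gfis(rbind(c(1, 0), c(1, 0))), ts))
  set.seed(9)
  for (i in 1:10) {
    th <- runif(4, -2, 2)
    m <- gfis(rbind(th[1:2], th[3:4]))
    expect_gte(gfis_objective(th, ts, cfg), gfis_rmse(m, ts) - 1e-12)
  }
  expect_error(gfis_objective(c(1, 2, 3), ts, cfg), "length")
})

test_that("fitting recovers a known generating model's outputs", {
  nd <- make_node_data(seed = 2)
  fit <- fit_gfis(nd$ts, fast_cfg())
  expect_lt(fit$rmse, 1e-3)
  expect_lt(fit$penalty, 1e-6)
  expect_equal(fit$objective, fit$rmse + fit$penalty, tolerance = 1e-12)
})

test_that("constant targets are fitted by a constant prediction", {
  x <- seq(0, 1, length.out = 9)
  fit <- suppressWarnings(fit_gfis(training_set(x, rep(0.4, 9)), fast_cfg()))
  expect_equal(unname(evaluate_gfis(fit$model, x)), rep(0.4, 9), tolerance = 1e-4)
})

test_that("fits are deterministic given the seed and improve with restarts", {
  nd <- make_node_data(seed = 4, sigma = 0.05)
  f1 <- fit_gfis(nd$ts, objective_config(n_restarts = 5, seed = 123))
  f2 <- fit_gfis(nd$ts, objective_config(n_restarts = 5, seed = 123))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$objective, f2$objective)
  # same seed stream: more restarts can only improve the selected objective
  objs <- vapply(1:6, function(k) {
    fit_gfis(nd$ts, objective_config(n_restarts = k, seed = 123))$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-15))
})

test_that("underdetermined training sets warn about the parameter count", {
  x <- seq(0, 1, length.out = 3)
  y <- evaluate_gfis(gfis(rbind(c(0.2, 0.1), c(0.1, 0.8))), x)
  expect_warning(fit_gfis(training_set(x, y), fast_cfg(n_restarts = 2)),
                 "free parameters")
})

test_that("the fast fitting path agrees with the exported objective", {
  nd <- make_node_data(seed = 6, sigma = 0.1)
  cfg <- fast_cfg()
  fit <- fit_gfis(nd$ts, cfg)
  expect_equal(fit$objective, gfis_objective(fit$theta, nd$ts, cfg),
               tolerance = 1e-12)
})
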