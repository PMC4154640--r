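test_that("Gaussian membership is 1 at the center and follows the closed form", {
  expect_equal(gauss_membership(0, center = 0, width = 0.4247), 1)
  expect_equal(gauss_membership(1, center = 1, width = 0.1), 1)
  expect_equal(gauss_membership(0.4247, center = 0, width = 0.4247), exp(-0.5))
  # symmetric about the center, strictly positive
  x <- seq(-3, 3, by = 0.25)
  expect_equal(gauss_membership(1 + x, 1, 0.5), gauss_membership(1 - x, 1, 0.5))
  expect_true(all(gauss_membership(x, 0, 0.4247) > 0))
  expect_error(gauss_membership(NaN, 0, 1), "finite")
  expect_error(gauss_membership(0.5, 0, 0), "width")
})

test_that("firing strengths are products of per-input memberships", {
  m1 <- gfis(rbind(c(1, 0), c(1, 0)))
  w <- firing_strengths(m1, 0)
  expect_equal(unname(w[1, "w1"]), 1)
  expect_equal(unname(w[1, "w2"]), exp(-1 / (2 * 0.4247^2)))
  m2 <- gfis(rbind(c(0, 0, 0), c(0, 0, 1)))
  w2 <- firing_strengths(m2, c(0, 0))
  expect_equal(unname(w2[1, "w1"]), 1)
  # at (0, 1) both rules share the same cross term by symmetry
  w01 <- firing_strengths(m2, c(0, 1))
  expect_equal(unname(w01[1, "w1"]), unname(w01[1, "w2"]))
  expect_error(firing_strengths(m2, c(0, 0, 0)), "expects 2 input")
})

test_that("evaluation matches hand-computed single-input cases", {
  ident <- gfis(rbind(c(1, 0), c(1, 0)))
  x <- seq(-0.5, 1.5, by = 0.1)
  expect_equal(evaluate_gfis(ident, x), x)
  # p1=p2=0, q1=0, q2=1 at x=0: w1=1, w2=exp(-1/(2*0.4247^2))
  step <- gfis(rbind(c(0, 0), c(0, 1)))
  w2 <- exp(-1 / (2 * 0.4247^2))
  expect_equal(evaluate_gfis(step, 0), w2 / (1 + w2))
  expect_equal(w2 / (1 + w2), 0.0625 / 1.0625, tolerance = 2e-3)
  # at the midpoint the two rules fire equally: plain average of consequents
  m <- gfis(rbind(c(0.3, -0.1), c(-0.5, 0.9)))
  f1 <- 0.3 * 0.5 - 0.1
  f2 <- -0.5 * 0.5 + 0.9
  expect_equal(evaluate_gfis(m, 0.5), (f1 + f2) / 2)
})

test_that("output is a convex combination of the two rule polynomials", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:3, 1)
    m <- random_gfis(n, free_premise = i %% 2 == 0)
    X <- matrix(runif(5 * n, -0.5, 1.5), 5, n)
    y <- evaluate_gfis(m, X)
    f1 <- X %*% m$consequents[1, 1:n] + m$consequents[1, n + 1]
    f2 <- X %*% m$consequents[2, 1:n] + m$consequents[2, n + 1]
    expect_true(all(y >= pmin(f1, f2) - 1e-12 & y <= pmax(f1, f2) + 1e-12))
  }
})

test_that("identical consequents in both rules collapse to that affine map", {
  cons <- c(0.7, -0.2, 0.4)
  m <- gfis(rbind(cons, cons))
  X <- matrix(runif(20, -1, 2), 10, 2)
  expect_equal(evaluate_gfis(m, X), drop(X %*% cons[1:2] + cons[3]))
})

test_that("evaluation agrees with the brute-force Takagi-Sugeno oracle", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:3, 1)
    m <- random_gfis(n, free_premise = TRUE)
    x <- runif(n, -0.5, 1.5)
    expect_equal(evaluate_gfis(m, x),
                 oracle_ts(m$centers, m$widths, m$consequents, x),
                 tolerance = 1e-13)
  }
})

test_that("parameter accounting reproduces the reduction-scheme counts", {
  g2 <- parameter_budget(2, "grid")
  expect_equal(g2$n_rules, 4)
  expect_equal(g2$n_free, 20)
  c2 <- parameter_budget(2, "constrained_rules")
  expect_equal(c2$n_rules, 2)
  expect_equal(c2$n_free, 14)
  expect_equal(parameter_budget(2, "fixed_premise")$n_free, 6)
  g1 <- parameter_budget(1, "grid")
  expect_equal(g1$n_premise_params + g1$n_consequent_params, 8)
  expect_equal(parameter_budget(1, "fixed_premise")$n_free, 4)
  for (n in 1:6) {
    expect_equal(parameter_budget(n, "fixed_premise")$n_free, 2 * (n + 1))
    expect_equal(parameter_budget(n, "grid")$n_rules, 2^n)
  }
  expect_error(parameter_budget(0, "grid"), "n_inputs")
})

test_that("a default gFIS carries the fixed premise values", {
  m <- gfis(rbind(c(1, 0), c(1, 0)))
  expect_equal(m$centers[1, 1], 0)
  expect_equal(m$centers[2, 1], 1)
  expect_equal(unique(as.vector(m$widths)), 0.4247)
  expect_equal(setup_free_params(1, "fixed_linear"), 4)
  expect_equal(setup_free_params(1, "adaptive_constant"), 6)
  expect_equal(setup_free_params(1, "adaptive_linear"), 8)
})
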