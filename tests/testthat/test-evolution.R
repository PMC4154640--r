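test_that("error evolution tabulates every node, condition and window", {
  g <- generate_scaled(toy_spec(seed = 41, noise_sigma = 0.02))
  ev <- evolve_network(g$data, toy_topology(), windows = c(48, 72, 96),
                       cfg = fast_cfg())
  expect_s3_class(ev, "error_evolution")
  expect_equal(nrow(ev), 3 * 2 * 3) # nodes x conditions x windows
  expect_true(all(ev$rmse >= 0))
  counts <- table(ev$node, ev$condition)
  expect_true(all(counts == 3))
  ev2 <- evolve_network(g$data, toy_topology(), windows = c(48, 72, 96),
                        cfg = fast_cfg())
  expect_identical(ev, ev2)
  expect_error(evolve_network(g$data, toy_topology(), windows = 96), "at least 2")
})

test_that("a stationary system keeps low, stable errors across windows", {
  g <- generate_scaled(toy_spec(seed = 43, noise_sigma = 0.02))
  ev <- evolve_network(g$data, toy_topology(), cfg = fast_cfg())
  spread <- tapply(ev$rmse, interaction(ev$node, ev$condition),
                   function(e) diff(range(e)))
  expect_true(all(spread < 0.1))
  expect_true(all(ev$rmse < 0.2))
})

test_that("classification follows the earliest/latest window errors", {
  ev <- data.frame(
    node = rep(c("ok", "static", "late"), each = 2),
    condition = "ctrl",
    window_end = rep(c(48, 96), 3),
    rmse = c(0.05, 0.05, # consistent
             0.30, 0.28, # high from the first window
             0.17851, 0.2141) # low early, high late
  )
  class(ev) <- c("error_evolution", "data.frame")
  fl <- classify_nodes(ev, threshold = 0.2)
  expect_equal(setNames(fl$label, fl$node)[c("ok", "static", "late")],
               c(ok = "consistent", static = "static_mismatch",
                 late = "rearrangement_candidate"))
})

test_that("errors exactly at the threshold are flagged", {
  ev <- data.frame(node = "X", condition = "c", window_end = c(48, 96),
                   rmse = c(0.1, 0.2))
  class(ev) <- c("error_evolution", "data.frame")
  expect_equal(classify_nodes(ev, 0.2)$label, "rearrangement_candidate")
  ev$rmse <- c(0.2, 0.2)
  expect_equal(classify_nodes(ev, 0.2)$label, "static_mismatch")
})

test_that("raising the threshold never un-flags into a worse class", {
  set.seed(47)
  severity <- c(consistent = 0, rearrangement_candidate = 1, static_mismatch = 2)
  for (i in 1:30) {
    ev <- data.frame(node = "N", condition = "c", window_end = c(48, 72, 96),
                     rmse = runif(3, 0, 0.5))
    class(ev) <- c("error_evolution", "data.frame")
    labs <- vapply(c(0.1, 0.2, 0.3, 0.5),
                   function(th) classify_nodes(ev, th)$label, character(1))
    expect_true(all(diff(severity[labs]) <= 0))
  }
})

test_that("an injected late regulator switch is flagged on the switched node", {
  ev <- rearrangement_event("T1", t_star = 48, type = "invert",
                            conditions = "drug")
  g <- generate_scaled(toy_spec(seed = 51, noise_sigma = 0.02, event = ev))
  tab <- evolve_network(g$data, toy_topology(), cfg = fast_cfg())
  fl <- classify_nodes(tab)
  expect_equal(fl$label[fl$node == "T1" & fl$condition == "drug"],
               "rearrangement_candidate")
  expect_true(all(fl$label[!(fl$node == "T1" & fl$condition == "drug")] ==
                    "consistent"))
})

test_that("a mis-wired regulator yields a static mismatch at every window", {
  # canonical identifiable mis-wiring: a Lissajous (1:2 frequency) pair, so
  # the claimed regulator genuinely cannot explain the node (see the methods
  # vignette for why generic smooth decoys are absorbed at 9 points)
  mis <- study_static_miswiring(seed = 53)
  expect_equal(mis$label, "static_mismatch")
  expect_true(all(mis$errors$rmse >= 0.2))
  expect_equal(nrow(mis$errors), 3)
})
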