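test_that("noiseless data are exactly reproduced by the recorded ground truth", {
  g <- generate_scaled(toy_spec(seed = 13))
  d <- g$data
  expect_true(all(d$value >= 0 & d$value <= 1))
  mx <- tapply(d$value, interaction(d$analyte, d$condition), max)
  expect_true(all(abs(mx - 1) < 1e-12))
  topo <- toy_topology()
  for (node in c("M1", "M2", "T1")) {
    for (cond in c("ctrl", "drug")) {
      ts <- training_subset(d, topo, node, cond)
      m <- gfis(g$truth$consequents[[node]][[cond]])
      expect_lt(max(abs(evaluate_gfis(m, ts$X) - ts$y)), 1e-12)
    }
  }
})

test_that("generation is deterministic given the seed", {
  a <- generate_scaled(toy_spec(seed = 17, noise_sigma = 0.05))
  b <- generate_scaled(toy_spec(seed = 17, noise_sigma = 0.05))
  expect_identical(a$data, b$data)
  c <- generate_scaled(toy_spec(seed = 18, noise_sigma = 0.05))
  expect_false(identical(a$data$value, c$data$value))
})

test_that("noise stays within the unit interval", {
  g <- generate_scaled(toy_spec(seed = 19, noise_sigma = 0.1))
  expect_true(all(g$data$value >= 0 & g$data$value <= 1))
})

test_that("a rearrangement event changes only post-switch behavior", {
  ev <- rearrangement_event("T1", t_star = 48, type = "constant_shift",
                            effect_size = 0.45)
  for (sigma in c(0, 0.02)) {
    base <- generate_scaled(toy_spec(seed = 23, noise_sigma = sigma))
    pert <- generate_scaled(toy_spec(seed = 23, noise_sigma = sigma, event = ev))
    pre <- base$data$time_h <= 48
    expect_identical(pert$data$value[pre], base$data$value[pre])
    t1_post <- with(base$data, analyte == "T1" & time_h > 48)
    expect_gt(mean(abs(pert$data$value[t1_post] - base$data$value[t1_post])),
              0.3)
  }
  expect_equal(pert <- generate_scaled(
    toy_spec(seed = 23, event = ev))$truth$event$t_star, 48)
})

test_that("event validation rejects malformed specifications", {
  expect_error(toy_spec(event = rearrangement_event("IN1", 48)), "non-input")
  expect_error(toy_spec(event = rearrangement_event("T1", 96)),
               "strictly inside")
  expect_error(rearrangement_event("T1", 48, type = "rewire"), "new_parent")
})

test_that("flip and rewire events perturb the target after the switch", {
  base <- generate_scaled(toy_spec(seed = 29))
  for (ev in list(rearrangement_event("T1", 48, type = "flip"),
                  rearrangement_event("T1", 48, type = "rewire",
                                      new_parent = "IN2"))) {
    pert <- generate_scaled(toy_spec(seed = 29, event = ev))
    pre <- base$data$time_h <= 48
    expect_identical(pert$data$value[pre], base$data$value[pre])
    post_t1 <- with(base$data, analyte == "T1" & time_h > 48)
    expect_false(isTRUE(all.equal(pert$data$value[post_t1],
                                  base$data$value[post_t1])))
  }
})

test_that("raw data round-trip through the preprocessing pipeline", {
  spec <- generator_spec(seed = 31, noise_sigma = 0.02)
  raw <- generate_raw(spec)
  expect_equal(nrow(raw$data), 10 * 9 * 4 * 2)
  expect_true(all(raw$data$value[raw$data$channel == "total"] > 0))
  scaled <- generate_scaled(spec)
  rt <- preprocess_dataset(raw$data)
  key <- function(d) d[order(d$analyte, d$condition, d$time_h), ]
  expect_equal(key(rt)$value, key(scaled$data)$value, tolerance = 1e-9)
})

test_that("fits on noiseless generated node data recover the outputs", {
  ok <- vapply(1:20, function(s) {
    g <- generate_scaled(toy_spec(seed = 100 + s))
    ts <- training_subset(g$data, toy_topology(), "M1", "ctrl")
    suppressWarnings(fit_gfis(ts, fast_cfg(seed = s))$rmse) <= 1e-3
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
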