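test_that("edge lists parse into validated topologies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("MEK1\tERK1/2", "ERK1/2\tCREB"), path)
  topo <- read_topology(path)
  expect_setequal(topo$nodes, c("MEK1", "ERK1/2", "CREB"))
  expect_equal(topo$input_nodes, "MEK1")
  expect_equal(topology_parents(topo, "CREB"), "ERK1/2")

  cyc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA"), cyc)
  expect_error(read_topology(cyc), "cycle.*A, B")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A\tB"), dup)
  expect_warning(t2 <- read_topology(dup), "duplicated")
  expect_equal(nrow(t2$edges), 1)
})

test_that("the bundled MAPK topologies differ in JNK's regulation", {
  init <- default_topology("initial")
  rew <- default_topology("rewired")
  expect_false("JNK" %in% init$input_nodes)
  expect_gte(length(topology_parents(init, "JNK")), 1)
  expect_true("JNK" %in% rew$input_nodes)
  expect_true(igraph::is_dag(init$graph))
})

test_that("training subsets intersect node and parent series within the window", {
  g <- generate_scaled(toy_spec(seed = 5))
  d <- g$data
  topo <- toy_topology()
  ts48 <- training_subset(d, topo, "M1", "ctrl", window_end = 48)
  expect_equal(ts48$times, c(0, 0.5, 6, 12, 24, 36, 48))
  expect_equal(colnames(ts48$X), "IN1")
  ts_all <- training_subset(d, topo, "M1", "ctrl")
  expect_equal(nrow(ts_all$X), 9)
  # a parent missing one time point drops that row with a warning
  d2 <- d[!(d$analyte == "IN1" & d$time_h == 24 & d$condition == "ctrl"), ]
  expect_warning(ts_drop <- training_subset(d2, topo, "M1", "ctrl"),
                 "dropping 1 time point")
  expect_equal(nrow(ts_drop$X), 8)
  expect_error(training_subset(d, topo, "IN1", "ctrl"), "input node")
})

test_that("network training fits one mtFIS per measured non-input node", {
  g <- generate_scaled(toy_spec(seed = 7))
  nm <- train_network(g$data, toy_topology(), cfg = fast_cfg())
  expect_setequal(names(nm$models), c("M1", "M2", "T1"))
  expect_equal(nrow(nm$fits), 3 * 2)
  expect_true(all(nm$fits$rmse <= 1e-3)) # noiseless recovery
  nm2 <- train_network(g$data, toy_topology(), cfg = fast_cfg())
  expect_identical(nm$models, nm2$models)
})

test_that("unmeasured topology nodes are excluded with a warning", {
  g <- generate_scaled(toy_spec(seed = 7))
  topo <- topology(rbind(toy_topology()$edges,
                         data.frame(regulator = "GHOST", target = "M2")))
  expect_warning(nm <- train_network(g$data, topo, cfg = fast_cfg()), "GHOST")
  expect_setequal(names(nm$models), c("M1", "M2", "T1"))
})

test_that("simulation maps inputs to data and propagates in topological order", {
  g <- generate_scaled(toy_spec(seed = 9))
  nm <- train_network(g$data, toy_topology(), cfg = fast_cfg())
  sim <- simulate_network(nm, g$data)
  inp <- sim[sim$node %in% c("IN1", "IN2"), ]
  expect_equal(inp$simulated, inp$observed)
  err <- node_errors(sim)
  expect_true(all(err$rmse <= 1e-3)) # depth-2 node recovered through the chain
  # node enumeration order does not matter, only the topology does
  edges_shuffled <- toy_topology()$edges[c(3, 1, 2), ]
  nm_sh <- train_network(g$data, topology(edges_shuffled), cfg = fast_cfg())
  sim_sh <- simulate_network(nm_sh, g$data)
  key <- function(s) s[order(s$node, s$condition, s$time_h), ]
  expect_equal(key(sim_sh)$simulated, key(sim)$simulated, tolerance = 1e-12)
})

test_that("corrupting an upstream model propagates error downstream", {
  g <- generate_scaled(toy_spec(seed = 11))
  nm <- train_network(g$data, toy_topology(), cfg = fast_cfg())
  base_err <- node_errors(simulate_network(nm, g$data))
  t1_base <- base_err$rmse[base_err$node == "T1"]
  # corrupt the mid-level model (M1): its child T1 should degrade
  bad <- nm
  for (cond in bad$conditions) {
    bad$models[["M1"]]$consequents[[cond]] <- rbind(c(0, 1), c(0, 0))
  }
  bad_err <- node_errors(simulate_network(bad, g$data))
  expect_gt(min(bad_err$rmse[bad_err$node == "T1"]), max(t1_base))
})

test_that("missing input observations stop the simulation", {
  g <- generate_scaled(toy_spec(seed = 9))
  nm <- train_network(g$data, toy_topology(), cfg = fast_cfg())
  d <- g$data[!(g$data$analyte == "IN1" & g$data$time_h == 36 &
                  g$data$condition == "ctrl"), ]
  expect_error(simulate_network(nm, d), "IN1.*36")
})

test_that("node errors reproduce direct RMSE computations", {
  sim <- data.frame(node = "B", condition = "c", time_h = 1:4,
                    simulated = 0.5, observed = c(0, 1, 0, 1))
  attr(sim, "input_nodes") <- character(0)
  class(sim) <- c("fl_simulation", "data.frame")
  expect_equal(node_errors(sim)$rmse, 0.5)
  sim$simulated <- sim$observed
  expect_equal(node_errors(sim)$rmse, 0)
  set.seed(3)
  sim$simulated <- runif(4)
  expect_equal(node_errors(sim, window_end = 3)$rmse,
               sqrt(mean((sim$simulated[1:3] - sim$observed[1:3])^2)))
})
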