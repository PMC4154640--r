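# Shared fixtures and an independent brute-force Takagi-Sugeno oracle.

# Brute-force first-order Takagi-Sugeno evaluation for the two-rule,
# two-fuzzy-sets models: scalar loops over rules and inputs, no shared code
# with evaluate_gfis().
oracle_ts <- function(centers, widths, consequents, x) {
  n <- length(x)
  num <- 0
  den <- 0
  for (r in 1:2) {
    w <- 1
    for (j in 1:n) {
      w <- w * exp(-(x[j] - centers[r, j])^2 / (2 * widths[r, j]^2))
    }
    f <- consequents[r, n + 1]
    for (j in 1:n) f <- f + consequents[r, j] * x[j]
    num <- num + w * f
    den <- den + w
  }
  num / den
}

random_gfis <- function(n, free_premise = FALSE) {
  cons <- matrix(runif(2 * (n + 1), -2, 2), 2, n + 1)
  if (!free_premise) return(gfis(cons))
  gfis(cons,
       centers = rbind(runif(n, -0.5, 0.5), runif(n, 0.5, 1.5)),
       widths = matrix(runif(2 * n, 0.1, 1), 2, n))
}

# Small training set generated from a known single-input gFIS on a smooth
# input sweep (noiseless unless sigma > 0).
make_node_data <- function(seed = 1, n_points = 9, sigma = 0,
                           consequents = rbind(c(0.1, 0.05), c(0.05, 0.85))) {
  set.seed(seed)
  x <- seq(0, 1, length.out = n_points) +
    rnorm(n_points, 0, 0.03)
  x <- pmin(pmax(x, 0), 1)
  truth <- gfis(consequents)
  y <- evaluate_gfis(truth, x)
  if (sigma > 0) y <- pmin(pmax(y + rnorm(n_points, 0, sigma), 0), 1)
  list(ts = training_set(x, y), truth = truth, x = x, y = y)
}

# 4-node toy topology: two input nodes, a middle node and a leaf.
#   IN1 -> M1 -> T1 ; IN2 -> M2
toy_topology <- function() {
  topology(data.frame(
    regulator = c("IN1", "M1", "IN2"),
    target = c("M1", "T1", "M2")
  ))
}

# Conditions kept small in unit tests to hold runtimes down.
fast_cfg <- function(seed = 1, n_restarts = 6) {
  objective_config(n_restarts = n_restarts, seed = seed)
}

toy_spec <- function(seed = 1, noise_sigma = 0, conditions = c("ctrl", "drug"),
                     event = NULL, topology = toy_topology()) {
  generator_spec(topology = topology, conditions = conditions,
                 noise_sigma = noise_sigma, event = event, seed = seed)
}
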