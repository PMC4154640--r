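#' Directed prior-knowledge topology
#'
#' A topology is a directed acyclic graph of regulator -> target interactions
#' assembled from the literature. Nodes with in-degree 0 are *input nodes*:
#' nothing measured regulates them, so they carry no model and are mapped to
#' their measured values during simulation. Edge direction encodes regulation
#' of the target by the regulator; the sign (activation vs inhibition) is not
#' part of the topology because the fitted consequent coefficients learn it.
#'
#' @param edges data.frame with columns `regulator` and `target` (one row per
#'   directed edge). Duplicated edges are removed with a warning; cycles are
#'   an error because synchronous propagation is only defined on acyclic
#'   graphs.
#' @return an object of class `"fl_topology"` with elements `nodes`, `edges`
#'   and `input_nodes`.
#' @seealso [read_topology()], [topology_parents()]
#' @export
topology <- function(edges) {
  check_columns(edges, c("regulator", "target"), "edges")
  edges <- data.frame(regulator = as.character(edges$regulator),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  if (nrow(edges) < 1L) stop_f("topology needs at least one edge")
  if (any(!nzchar(edges$regulator)) || any(!nzchar(edges$target))) {
    stop_f("empty node names are not allowed")
  }
  dup <- duplicated(edges)
  if (any(dup)) {
    warn_f("removing %d duplicated edge(s)", sum(dup))
    edges <- edges[!dup, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    if (!length(cyc)) cyc <- edges$regulator[edges$regulator == edges$target]
    stop_f("topology contains a cycle involving: %s",
           paste(sort(unique(cyc)), collapse = ", "))
  }
  nodes <- sort(igraph::V(g)$name)
  indeg <- igraph::degree(g, mode = "in")
  structure(
    list(nodes = nodes,
         edges = edges,
         input_nodes = sort(names(indeg)[indeg == 0]),
         graph = g),
    class = "fl_topology"
  )
}

#' Read a topology from a two-column tab-separated edge list
#'
#' Each non-comment line is `regulator<TAB>target`. Lines starting with `#`
#' and an optional `regulator\ttarget` header line are ignored.
#'
#' @param path path to the TSV file.
#' @return an [topology()] object.
#' @examples
#' path <- system.file("extdata", "topology_initial.tsv", package = "fuzzlink")
#' topo <- read_topology(path)
#' topo$input_nodes
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop_f("topology file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, col.names = c("regulator", "target"))
  if (nrow(df) && identical(tolower(unlist(df[1, ])),
                            c(regulator = "regulator", target = "target"))) {
    df <- df[-1, , drop = FALSE]
  }
  topology(df)
}

#' @export
print.fl_topology <- function(x, ...) {
  cat(sprintf("topology: %d nodes, %d edges; input nodes: %s\n",
              length(x$nodes), nrow(x$edges),
              paste(x$input_nodes, collapse = ", ")))
  invisible(x)
}

#' Regulators of a node, in the fixed model input order
#'
#' Parents are returned sorted lexicographically; this is the column order of
#' every training matrix and the input order of every fitted model, so
#' consequent coefficients are unambiguous across runs.
#'
#' @param topo an [topology()] object.
#' @param node node name.
#' @return character vector of parent names (empty for input nodes).
#' @export
topology_parents <- function(topo, node) {
  stopifnot(inherits(topo, "fl_topology"))
  if (!node %in% topo$nodes) stop_f("node '%s' is not in the topology", node)
  sort(topo$edges$regulator[topo$edges$target == node])
}

check_scaled <- function(data) {
  check_columns(data, c("analyte", "condition", "time_h", "value"), "data")
  if (any(!is.finite(data$value))) stop_f("scaled values must be finite")
  invisible(data)
}

#' Extract the training subset for one node and condition
#'
#' Rows are the time points at or before `window_end` at which the node and
#' all of its regulators were measured in the given condition. Time points
#' missing from any of the involved series are dropped with a warning
#' (intersection semantics); the method tolerates irregular sampling because
#' each model is a static input -> output map.
#'
#' @param data scaled measurements (`analyte`, `condition`, `time_h`,
#'   `value`), as produced by [preprocess_dataset()] or [generate_scaled()].
#' @param topo an [topology()] object.
#' @param node a non-input node of `topo`.
#' @param condition condition label present in `data`.
#' @param window_end training window upper bound in hours (default `Inf`:
#'   all time points).
#' @return a [training_set()] whose `X` columns follow
#'   [topology_parents()] order.
#' @export
training_subset <- function(data, topo, node, condition, window_end = Inf) {
  check_scaled(data)
  stopifnot(inherits(topo, "fl_topology"))
  parents <- topology_parents(topo, node)
  if (!length(parents)) {
    stop_f("node '%s' is an input node: it has no regulators to train on", node)
  }
  d <- data[data$condition == condition & data$time_h <= window_end, , drop = FALSE]
  series <- lapply(c(node, parents), function(a) {
    s <- d[d$analyte == a, , drop = FALSE]
    if (!nrow(s)) {
      stop_f("no measurements for '%s' in condition '%s' (window <= %s h)",
             a, condition, format(window_end))
    }
    s[order(s$time_h), , drop = FALSE]
  })
  names(series) <- c(node, parents)
  times <- Reduce(intersect, lapply(series, function(s) s$time_h))
  all_times <- sort(unique(unlist(lapply(series, function(s) s$time_h))))
  if (length(times) < length(all_times)) {
    warn_f("node '%s' (%s): dropping %d time point(s) not measured in all involved series",
           node, condition, length(all_times) - length(times))
  }
  if (length(times) < 2L) {
    stop_f("node '%s' (%s): fewer than 2 complete time points at window <= %s h",
           node, condition, format(window_end))
  }
  times <- sort(times)
  grab <- function(a) series[[a]]$value[match(times, series[[a]]$time_h)]
  X <- vapply(parents, grab, numeric(length(times)))
  X <- matrix(X, ncol = length(parents), dimnames = list(NULL, parents))
  training_set(X, grab(node), times = times, node = node, condition = condition)
}

# Restrict a topology to the analytes actually measured; warns about nodes
# that appear in the literature network but not in the dataset.
measured_topology <- function(topo, data) {
  measured <- unique(data$analyte)
  missing <- setdiff(topo$nodes, measured)
  if (length(missing)) {
    warn_f("excluding unmeasured topology node(s): %s",
           paste(missing, collapse = ", "))
    keep <- topo$edges$regulator %in% measured & topo$edges$target %in% measured
    if (!any(keep)) stop_f("no topology edge connects two measured analytes")
    topo <- topology(topo$edges[keep, , drop = FALSE])
  }
  topo
}

#' Train one multi-treatment model per non-input node
#'
#' For every non-input node of the topology and every condition, the node's
#' training subset ([training_subset()]) is fitted with [fit_gfis()]; the
#' per-condition fits are then assembled into an [assemble_mtfis()] model.
#' Topology nodes that are not measured in the data are excluded with a
#' warning. Fit seeds are derived from `cfg$seed` plus a per-(node,
#' condition) offset, so the result is deterministic given the seed.
#'
#' @inheritParams training_subset
#' @param window_end training window upper bound in hours; only measurements
#'   at `time_h <= window_end` are used (default `Inf`).
#' @param cfg an [objective_config()].
#' @param conditions conditions to train on (default: all conditions in the
#'   data, sorted).
#' @return an object of class `"fl_network"` with elements `topology`
#'   (restricted to measured nodes), `conditions`, `models` (named list of
#'   mtFIS), `fits` (per node/condition training diagnostics) and
#'   `window_end`.
#' @export
train_network <- function(data, topo, window_end = Inf,
                          cfg = objective_config(), conditions = NULL) {
  check_scaled(data)
  topo <- measured_topology(topo, data)
  if (is.null(conditions)) conditions <- sort(unique(data$condition))
  targets <- setdiff(topo$nodes, topo$input_nodes)
  if (!length(targets)) stop_f("topology has no trainable (non-input) node")
  models <- list()
  fits <- list()
  for (ni in seq_along(targets)) {
    node <- targets[ni]
    per_condition <- list()
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      ts <- training_subset(data, topo, node, cond, window_end)
      fit_cfg <- cfg
      fit_cfg$seed <- cfg$seed + 1000L * ((ni - 1L) * length(conditions) + ci - 1L)
      fit <- tryCatch(
        fit_gfis(ts, fit_cfg),
        error = function(e) {
          stop_f("fit failed for node '%s', condition '%s': %s",
                 node, cond, conditionMessage(e))
        }
      )
      per_condition[[cond]] <- fit
      fits[[length(fits) + 1L]] <- data.frame(
        node = node, condition = cond, rmse = fit$rmse,
        penalty = fit$penalty, objective = fit$objective,
        n_obs = fit$n_obs, stringsAsFactors = FALSE
      )
    }
    models[[node]] <- assemble_mtfis(per_condition)
  }
  structure(
    list(topology = topo, conditions = conditions, models = models,
         fits = do.call(rbind, fits), window_end = window_end,
         seed = cfg$seed),
    class = "fl_network"
  )
}

#' @export
print.fl_network <- function(x, ...) {
  cat(sprintf("network model: %d trained node(s) x %d condition(s), window <= %s h\n",
              length(x$models), length(x$conditions), format(x$window_end)))
  print(x$topology)
  invisible(x)
}

#' Simulate the trained network synchronously
#'
#' At each observed time point, input nodes take their measured value (the
#' mapping function) and every other node is evaluated, in topological order,
#' on the *simulated* values of its regulators under the active condition.
#' Each time point is an independent static evaluation; no state is carried
#' between time points.
#'
#' @param nm an [train_network()] model.
#' @param data scaled measurements used for the input-node mapping and for
#'   the matched observed values.
#' @param conditions conditions to simulate (default: all the model was
#'   trained on).
#' @return a data.frame of class `"fl_simulation"` with columns `node`,
#'   `condition`, `time_h`, `simulated` and `observed` (`NA` when the node
#'   was not measured at that time point). Input nodes appear with
#'   `simulated == observed`.
#' @export
simulate_network <- function(nm, data, conditions = NULL) {
  stopifnot(inherits(nm, "fl_network"))
  check_scaled(data)
  if (is.null(conditions)) conditions <- nm$conditions
  topo <- nm$topology
  order_nodes <- igraph::V(topo$graph)$name[
    as.integer(igraph::topo_sort(topo$graph, mode = "out"))]
  out <- list()
  for (cond in conditions) {
    d <- data[data$condition == cond & data$analyte %in% topo$nodes, , drop = FALSE]
    if (!nrow(d)) stop_f("no measurements for condition '%s'", cond)
    times <- sort(unique(d$time_h))
    obs <- matrix(NA_real_, length(times), length(topo$nodes),
                  dimnames = list(NULL, topo$nodes))
    idx <- cbind(match(d$time_h, times), match(d$analyte, topo$nodes))
    obs[idx] <- d$value
    for (inp in topo$input_nodes) {
      miss <- times[is.na(obs[, inp])]
      if (length(miss)) {
        stop_f("input node '%s' has no observation at t = %s h (condition '%s')",
               inp, paste(miss, collapse = ", "), cond)
      }
    }
    sim <- obs
    sim[, setdiff(topo$nodes, topo$input_nodes)] <- NA_real_
    for (node in order_nodes) {
      if (node %in% topo$input_nodes) next
      parents <- topology_parents(topo, node)
      X <- sim[, parents, drop = FALSE]
      sim[, node] <- evaluate_mtfis(nm$models[[node]], X, cond)
    }
    out[[cond]] <- data.frame(
      node = rep(topo$nodes, each = length(times)),
      condition = cond,
      time_h = rep(times, times = length(topo$nodes)),
      simulated = as.vector(sim),
      observed = as.vector(obs),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "input_nodes") <- topo$input_nodes
  class(res) <- c("fl_simulation", "data.frame")
  res
}

#' Per-node, per-condition simulation error
#'
#' RMSE of simulated against observed values over the time points at or
#' before `window_end` — the model's own training window, so that the error
#' of a 48 h model is not conflated with its extrapolation beyond 48 h.
#' Input nodes are excluded (they reproduce the data by construction).
#'
#' @param sim a [simulate_network()] result.
#' @param window_end upper bound (hours) of the evaluation window.
#' @return data.frame with columns `node`, `condition`, `rmse`, `n_points`,
#'   `window_end`.
#' @export
node_errors <- function(sim, window_end = Inf) {
  stopifnot(inherits(sim, "fl_simulation"))
  input_nodes <- attr(sim, "input_nodes")
  d <- sim[sim$time_h <= window_end & !is.na(sim$observed) &
             !(sim$node %in% input_nodes), , drop = FALSE]
  if (!nrow(d)) stop_f("no evaluable simulated points at window <= %s h", format(window_end))
  key <- interaction(d$node, d$condition, drop = TRUE)
  res <- do.call(rbind, lapply(split(d, key), function(g) {
    data.frame(node = g$node[1L], condition = g$condition[1L],
               rmse = sqrt(mean((g$simulated - g$observed)^2)),
               n_points = nrow(g), window_end = window_end,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res[order(res$node, res$condition), , drop = FALSE]
}
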