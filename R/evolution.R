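#' Error evolution over nested training windows
#'
#' Retrains and simulates the full network once per training window (e.g. 48,
#' 72 and 96 h), evaluating each window's models against their own training
#' window. The resulting node x condition x window RMSE table is the input of
#' [classify_nodes()]: a node whose error is high from the earliest window on
#' points at a statically wrong topology, while a node whose error only
#' appears in late windows is a candidate for a signaling rearrangement
#' acquired during the observation.
#'
#' @inheritParams train_network
#' @param windows increasing vector of window end points in hours (>= 2
#'   windows). Each window uses measurements at `time_h <= windows[i]`.
#' @return a data.frame of class `"error_evolution"` with columns `node`,
#'   `condition`, `window_end`, `rmse`, `n_points`.
#' @seealso [classify_nodes()]
#' @export
evolve_network <- function(data, topo, windows = c(48, 72, 96),
                           cfg = objective_config(), conditions = NULL) {
  if (length(windows) < 2L) stop_f("need at least 2 training windows")
  windows <- sort(as.numeric(windows))
  if (anyDuplicated(windows)) stop_f("windows must be distinct")
  out <- lapply(windows, function(w) {
    nm <- tryCatch(
      train_network(data, topo, window_end = w, cfg = cfg,
                    conditions = conditions),
      error = function(e) stop_f("window %s h: %s", format(w), conditionMessage(e))
    )
    sim <- simulate_network(nm, data, conditions = nm$conditions)
    err <- node_errors(sim, window_end = w)
    err[, c("node", "condition", "window_end", "rmse", "n_points")]
  })
  res <- do.call(rbind, out)
  res <- res[order(res$node, res$condition, res$window_end), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("error_evolution", "data.frame")
  res
}

#' Classify nodes from their error evolution
#'
#' Three-way classification of each (node, condition) from the earliest- and
#' latest-window errors, mirroring the two-axis region-of-confidence reading
#' of the error-evolution plane:
#' \describe{
#'   \item{`static_mismatch`}{earliest-window RMSE >= `threshold`: the model
#'     disagrees with the data from the start, so the assumed topology is
#'     likely wrong for this node.}
#'   \item{`rearrangement_candidate`}{earliest-window RMSE < `threshold` but
#'     latest-window RMSE >= `threshold`: the model captures the early data
#'     and fails once late time points are included — a time-defined
#'     rearrangement.}
#'   \item{`consistent`}{both below `threshold`.}
#' }
#' Errors exactly at the threshold count as high: below the threshold is the
#' accurate regime, so the boundary goes to the flagged side. Intermediate
#' windows are reported for inspection but do not drive the label.
#'
#' @param ev an [evolve_network()] table.
#' @param threshold RMSE above which a model is considered in disagreement
#'   with its data (default 0.2).
#' @return data.frame with one row per (node, condition): `label` (one of
#'   `consistent`, `static_mismatch`, `rearrangement_candidate`),
#'   `rmse_first`, `rmse_last` and the corresponding window ends.
#' @export
classify_nodes <- function(ev, threshold = 0.2) {
  stopifnot(inherits(ev, "data.frame"))
  check_columns(ev, c("node", "condition", "window_end", "rmse"), "ev")
  check_number(threshold, "threshold", min = 0)
  w_first <- min(ev$window_end)
  w_last <- max(ev$window_end)
  key <- interaction(ev$node, ev$condition, drop = TRUE)
  res <- do.call(rbind, lapply(split(ev, key), function(g) {
    if (!all(c(w_first, w_last) %in% g$window_end)) {
      stop_f("incomplete error-evolution table for node '%s' (%s)",
             g$node[1L], g$condition[1L])
    }
    e1 <- g$rmse[g$window_end == w_first]
    e2 <- g$rmse[g$window_end == w_last]
    label <- if (e1 >= threshold) {
      "static_mismatch"
    } else if (e2 >= threshold) {
      "rearrangement_candidate"
    } else {
      "consistent"
    }
    data.frame(node = g$node[1L], condition = g$condition[1L], label = label,
               rmse_first = e1, rmse_last = e2,
               window_first = w_first, window_last = w_last,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res[order(res$node, res$condition), , drop = FALSE]
}
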