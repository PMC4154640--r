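# Model bundles (JSON), result tables (CSV) and run configuration.

MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize a trained network model to JSON
#'
#' The bundle stores the topology, the per-node mtFIS parameters (premises
#' and per-condition consequent blocks) and the training window, at full
#' double precision, so a reloaded model simulates bit-identically.
#'
#' @param nm an [train_network()] model.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @seealso [read_network_model()]
#' @export
write_network_model <- function(nm, path) {
  stopifnot(inherits(nm, "fl_network"))
  bundle <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    generator = "fuzzlink",
    window_end = if (is.finite(nm$window_end)) nm$window_end else NULL,
    seed = nm$seed,
    conditions = as.list(nm$conditions),
    edges = nm$topology$edges,
    models = lapply(names(nm$models), function(node) {
      m <- nm$models[[node]]
      list(node = node,
           parents = as.list(topology_parents(nm$topology, node)),
           centers = m$centers,
           widths = m$widths,
           consequents = m$consequents)
    }),
    fits = nm$fits
  )
  # I(17) = 17 significant digits: doubles survive the round trip exactly
  jsonlite::write_json(bundle, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a network model bundle
#'
#' @param path JSON file written by [write_network_model()].
#' @return an `"fl_network"` object equivalent to the serialized one; its
#'   simulations are bit-identical to the original model's.
#' @export
read_network_model <- function(path) {
  if (!file.exists(path)) stop_f("model bundle not found: %s", path)
  b <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(b$schema_version, MODEL_SCHEMA_VERSION)) {
    stop_f("model bundle schema version '%s' is not supported (expected '%s')",
           paste(b$schema_version, collapse = ""), MODEL_SCHEMA_VERSION)
  }
  required <- c("conditions", "edges", "models")
  missing <- setdiff(required, names(b))
  if (length(missing)) {
    stop_f("model bundle is missing field(s): %s", paste(missing, collapse = ", "))
  }
  field <- function(rows, name) vapply(rows, function(r) r[[name]], character(1))
  topo <- topology(data.frame(regulator = field(b$edges, "regulator"),
                              target = field(b$edges, "target"),
                              stringsAsFactors = FALSE))
  conditions <- as.character(b$conditions)
  models <- list()
  for (m in b$models) {
    per_condition <- lapply(m$consequents, function(cc) {
      gfis(as.matrix(cc), centers = as.matrix(m$centers),
           widths = as.matrix(m$widths))
    })
    models[[m$node]] <- assemble_mtfis(per_condition)
  }
  fits <- if (!is.null(b$fits)) {
    do.call(rbind, lapply(b$fits, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(topology = topo, conditions = conditions, models = models,
         fits = fits,
         window_end = if (is.null(b$window_end)) Inf else b$window_end,
         seed = b$seed),
    class = "fl_network"
  )
}

#' Write / read an error-evolution table
#'
#' Plain CSV with a stable column order (`node`, `condition`, `window_end`,
#' `rmse`, `n_points`).
#'
#' @param ev an [evolve_network()] table.
#' @param path CSV path.
#' @return `path` (write) or the table with its `error_evolution` class
#'   restored (read).
#' @export
write_error_evolution <- function(ev, path) {
  check_columns(ev, c("node", "condition", "window_end", "rmse"), "ev")
  cols <- intersect(c("node", "condition", "window_end", "rmse", "n_points"),
                    names(ev))
  write.csv(ev[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_error_evolution
#' @export
read_error_evolution <- function(path) {
  if (!file.exists(path)) stop_f("file not found: %s", path)
  ev <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(ev, c("node", "condition", "window_end", "rmse"), "ev")
  class(ev) <- c("error_evolution", "data.frame")
  ev
}

#' Write node classification flags
#'
#' @param flags a [classify_nodes()] table.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_node_flags <- function(flags, path) {
  check_columns(flags, c("node", "condition", "label"), "flags")
  write.csv(flags, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Default run parameters (optimizer restarts, interpolation points,
#' bootstrap resamples, training windows, disagreement threshold), optionally
#' overridden from a JSON file and/or by named arguments.
#'
#' @param path optional JSON file whose top-level fields override the
#'   defaults.
#' @param ... named overrides applied after the file.
#' @return a list of class `"run_config"` with fields `seed`, `n_restarts`,
#'   `n_interp`, `bootstrap_B`, `windows`, `threshold`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(seed = 1L, n_restarts = 20L, n_interp = 20L, bootstrap_B = 100L,
              windows = c(48, 72, 96), threshold = 0.2)
  apply_overrides <- function(cfg, over, where) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop_f("unknown run_config field(s) %s in %s",
             paste(unknown, collapse = ", "), where)
    }
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop_f("config file not found: %s", path)
    cfg <- apply_overrides(cfg, jsonlite::read_json(path, simplifyVector = TRUE),
                           path)
  }
  over <- list(...)
  if (length(over)) cfg <- apply_overrides(cfg, over, "arguments")
  check_number(cfg$threshold, "threshold", min = 0)
  structure(cfg, class = "run_config")
}

# objective_config view of a run_config
as_objective_config <- function(rc, seed = NULL) {
  objective_config(n_interp = rc$n_interp, n_restarts = rc$n_restarts,
                   seed = if (is.null(seed)) rc$seed else seed)
}
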