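# Synthetic datasets with the statistical structure the modeling pipeline
# assumes: smooth input-node trajectories on [0, 1], downstream nodes
# generated by known gFIS ground-truth models per condition, truncated
# Gaussian measurement noise, and optional injected rearrangement events.

#' Bundled literature-derived MAPK topology
#'
#' Two variants of a representative literature-derived MAPK prior-knowledge
#' network over the 10-analyte readout panel (MEK1, ERK1/2, CREB, Akt, JNK,
#' c-Jun, IKK, P38, P53, ATF-2). In the `"initial"` variant JNK is regulated
#' by Akt; the `"rewired"` variant removes that edge, making JNK an input
#' node regulated independently of Akt.
#'
#' @param variant `"initial"` or `"rewired"`.
#' @return an [topology()] object.
#' @export
default_topology <- function(variant = c("initial", "rewired")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", paste0("topology_", variant, ".tsv"),
                      package = "fuzzlink", mustWork = TRUE)
  read_topology(path)
}

#' Describe an injected rearrangement event
#'
#' A rearrangement event swaps the generating model of one node for all time
#' points strictly after `t_star`. Descendants of the node keep their own
#' ground-truth models but see the perturbed values, so the perturbation
#' propagates downstream exactly as a real rewiring would.
#'
#' Event types:
#' \describe{
#'   \item{`invert`}{the post-switch generating model is a gFIS with
#'     identical affine consequents fitted to the *opposite-extreme* targets
#'     (`1 - round(baseline value)`) at the post-switch points: the node's
#'     response saturates at the far end of the scale from wherever its
#'     baseline response was. This is the strongest-contrast rearrangement;
#'     every post-switch point is displaced by at least 0.5 scaled units.}
#'   \item{`constant_shift`}{the post-switch generating model is a constant
#'     (zero-slope) model displaced from the node's post-switch baseline mean
#'     by `effect_size` scaled units (towards the far end of the [0, 1]
#'     range).}
#'   \item{`flip`}{the post-switch consequents are the complement of the
#'     baseline ones (`p -> -p`, `q -> 1 - q`), i.e. the node's response is
#'     inverted.}
#'   \item{`rewire`}{the node follows a freshly sampled single-input model of
#'     `new_parent` after `t_star` (a replacement regulator).}
#' }
#'
#' @param node name of the perturbed node (must be a non-input node).
#' @param t_star switch time in hours, strictly inside the time grid.
#' @param type event type, see Details.
#' @param effect_size displacement of the post-switch mean, in scaled units
#'   (used by `constant_shift`).
#' @param new_parent replacement regulator (required for `type = "rewire"`).
#' @param conditions conditions the event applies to (default `NULL`: all),
#'   mirroring treatment-specific rearrangements.
#' @return a list of class `"rearrangement_event"`.
#' @export
rearrangement_event <- function(node, t_star = 48,
                                type = c("invert", "constant_shift", "flip",
                                         "rewire"),
                                effect_size = 0.45, new_parent = NULL,
                                conditions = NULL) {
  type <- match.arg(type)
  check_number(t_star, "t_star")
  check_number(effect_size, "effect_size", min = 0)
  if (type == "rewire" && is.null(new_parent)) {
    stop_f("a 'rewire' event needs `new_parent`")
  }
  structure(
    list(node = node, t_star = t_star, type = type,
         effect_size = effect_size, new_parent = new_parent,
         conditions = conditions),
    class = "rearrangement_event"
  )
}

#' Specification of a synthetic dataset
#'
#' Defaults emulate the modeled experimental design: a 10-analyte MAPK panel
#' measured at 9 time points over 4 days under a solvent control and three
#' kinase-inhibitor treatments, on the normalized, max-scaled [0, 1] scale.
#'
#' @param topology an [topology()] object (default: the bundled initial MAPK
#'   topology).
#' @param conditions character vector of condition labels (default the 4
#'   treatment arms).
#' @param times time grid in hours (default 0, 0.5, 6, 12, 24, 36, 48, 72,
#'   96).
#' @param noise_sigma standard deviation of the additive Gaussian measurement
#'   noise on scaled values (truncated to [0, 1]); default 0.02.
#' @param event optional [rearrangement_event()].
#' @param seed master seed. All stage seeds (input trajectories, ground-truth
#'   consequents, event models, noise) are derived from it, and noise draws
#'   are independent of the presence of an event.
#' @param input_params optional pinned input trajectories: a named list
#'   mapping an input-node name to a list with fields `base`, `slope`, `amp`,
#'   `freq`, `phase` (trend plus sinusoid coefficients, frequency in cycles
#'   per observation window). Pinned nodes use these parameters in every
#'   condition instead of the seeded random draw; useful for studies that
#'   need a controlled geometric relationship between two trajectories.
#' @return a list of class `"generator_spec"`.
#' @export
generator_spec <- function(topology = default_topology(),
                           conditions = c("DMSO", "U0126", "AZD6244", "Sorafenib"),
                           times = c(0, 0.5, 6, 12, 24, 36, 48, 72, 96),
                           noise_sigma = 0.02, event = NULL, seed = 1L,
                           input_params = NULL) {
  stopifnot(inherits(topology, "fl_topology"))
  check_number(noise_sigma, "noise_sigma", min = 0)
  check_number(seed, "seed")
  times <- sort(unique(as.numeric(times)))
  if (length(times) < 3L || any(times < 0)) {
    stop_f("`times` must be >= 3 distinct non-negative hours")
  }
  if (length(conditions) < 1L || anyDuplicated(conditions)) {
    stop_f("`conditions` must be distinct labels")
  }
  if (!is.null(event)) {
    stopifnot(inherits(event, "rearrangement_event"))
    if (!event$node %in% setdiff(topology$nodes, topology$input_nodes)) {
      stop_f("event node '%s' must be a non-input topology node", event$node)
    }
    if (event$t_star <= min(times) || event$t_star >= max(times)) {
      stop_f("event t_star must lie strictly inside the time grid")
    }
    if (!is.null(event$new_parent) &&
        (!event$new_parent %in% topology$nodes ||
         identical(event$new_parent, event$node))) {
      stop_f("event new_parent must be a topology node different from the event node")
    }
    if (!is.null(event$conditions) &&
        !all(event$conditions %in% conditions)) {
      stop_f("event conditions must be a subset of the dataset conditions")
    }
  }
  if (!is.null(input_params)) {
    if (is.null(names(input_params)) ||
        !all(names(input_params) %in% topology$input_nodes)) {
      stop_f("input_params names must be input nodes of the topology")
    }
    fields <- c("base", "slope", "amp", "freq", "phase")
    ok <- vapply(input_params, function(p) all(fields %in% names(p)), logical(1))
    if (!all(ok)) {
      stop_f("each input_params entry needs fields: %s",
             paste(fields, collapse = ", "))
    }
  }
  structure(
    list(topology = topology, conditions = as.character(conditions),
         times = times, noise_sigma = noise_sigma, event = event,
         seed = as.integer(seed), input_params = input_params),
    class = "generator_spec"
  )
}

# Smooth trajectory in (0, 1] touching 1: low-order trend plus a bounded
# sinusoid, clamped and divided by its maximum. Pure noise would leave the
# interpolation penalty untested; these curves sweep a real range. The
# frequency range guarantees at least one full oscillation over the
# observation window, so late-time input values revisit the range explored
# early on — without that, a late regulator switch is not identifiable: the
# fitted map can bend freely in input regions visited only after the switch.
input_trajectory <- function(par, times) {
  tmax <- max(times)
  v <- par$base + par$slope * times / tmax +
    par$amp * sin(2 * pi * par$freq * times / tmax + par$phase)
  v <- pmin(pmax(v, 0.02), 1)
  v / max(v)
}

sample_input_params <- function() {
  list(base = runif(1, 0.3, 0.6), slope = runif(1, -0.15, 0.15),
       amp = runif(1, 0.2, 0.35), freq = runif(1, 1.2, 2.2),
       phase = runif(1, 0, 2 * pi))
}

# Ground-truth consequents with a large dynamic range and outputs guaranteed
# inside (0, 1) for inputs in [0, 1]: the low rule stays near the floor, the
# high rule near the ceiling.
sample_consequents <- function(n) {
  q1 <- runif(1, 0.05, 0.15)
  p1 <- runif(n, -q1 / (2 * n), q1 / (2 * n))
  q2 <- runif(1, 0.75, 0.9)
  p2 <- runif(n, 0, (1 - q2) / n)
  rbind(c(p1, q1), c(p2, q2))
}

stage_seeds <- function(seed, n = 5L) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Generate a synthetic scaled dataset with known ground truth
#'
#' Input-node trajectories are smooth curves in [0, 1]; every non-input node
#' is produced by topological-order evaluation of its ground-truth gFIS on
#' its parents' values, per condition and time point. Ground-truth
#' consequents are rescaled during construction so every noiseless series
#' attains a maximum of exactly 1 while still being generated exactly by the
#' recorded models. Measurement noise (`N(0, noise_sigma)`, truncated to
#' [0, 1]) is then added, and each series is divided by its maximum — the
#' same final step as the preprocessing pipeline, so generated data satisfy
#' the scaled-data contract. With an event, pre-switch values match the
#' matching no-event dataset point-for-point: noise draws and scale factors
#' are taken from the no-event baseline.
#'
#' @param spec a [generator_spec()].
#' @return a list of class `"synthetic_dataset"` with `data` (scaled
#'   measurements: `analyte`, `condition`, `time_h`, `value`) and `truth`
#'   (input trajectory parameters, per-node/condition generating consequents,
#'   event models, per-series scale factors and the spec itself).
#' @export
generate_scaled <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  topo <- spec$topology
  times <- spec$times
  conds <- spec$conditions
  seeds <- stage_seeds(spec$seed)
  nodes_topo <- igraph::V(topo$graph)$name[
    as.integer(igraph::topo_sort(topo$graph, mode = "out"))]
  targets <- setdiff(nodes_topo, topo$input_nodes)

  # stage 1: input-node trajectories (seeded draws, then pinned overrides)
  input_params <- with_local_seed(seeds[1L], {
    out <- list()
    for (cond in conds) {
      for (inp in sort(topo$input_nodes)) {
        out[[cond]][[inp]] <- sample_input_params()
      }
    }
    out
  })
  for (inp in names(spec$input_params)) {
    for (cond in conds) input_params[[cond]][[inp]] <- spec$input_params[[inp]]
  }

  # stage 2: ground-truth consequents (pre-normalization), fixed draw order
  consequents <- with_local_seed(seeds[2L], {
    out <- list()
    for (node in targets) {
      n <- length(topology_parents(topo, node))
      for (cond in conds) out[[node]][[cond]] <- sample_consequents(n)
    }
    out
  })

  # baseline (no-event) evaluation in topological order; normalize each
  # node/condition model so its noiseless series peaks at exactly 1
  base_vals <- list()
  for (cond in conds) {
    vals <- matrix(NA_real_, length(times), length(topo$nodes),
                   dimnames = list(NULL, topo$nodes))
    for (inp in topo$input_nodes) {
      vals[, inp] <- input_trajectory(input_params[[cond]][[inp]], times)
    }
    for (node in targets) {
      parents <- topology_parents(topo, node)
      y <- evaluate_gfis(gfis(consequents[[node]][[cond]]),
                         vals[, parents, drop = FALSE])
      consequents[[node]][[cond]] <- consequents[[node]][[cond]] / max(y)
      # re-evaluate with the normalized consequents so baseline values share
      # the exact floating-point path of the event pass
      vals[, node] <- pmin(pmax(
        evaluate_gfis(gfis(consequents[[node]][[cond]]),
                      vals[, parents, drop = FALSE]), 0), 1)
    }
    base_vals[[cond]] <- vals
  }

  # stage 3: event pass (perturbed node swaps model after t_star; descendants
  # keep their models but see the perturbed values)
  event <- spec$event
  event_truth <- NULL
  event_vals <- base_vals
  if (!is.null(event)) {
    post <- times > event$t_star
    event_conds <- if (is.null(event$conditions)) conds else event$conditions
    rewire_cons <- if (event$type == "rewire") {
      with_local_seed(seeds[3L], {
        out <- list()
        for (cond in conds) out[[cond]] <- sample_consequents(1L)
        out
      })
    }
    post_models <- list()
    for (cond in event_conds) {
      vals <- base_vals[[cond]]
      base_node <- vals[, event$node]
      parents_ev <- topology_parents(topo, event$node)
      post_y <- switch(event$type,
        invert = {
          # affine consequents through the opposite-extreme targets
          tgt <- 1 - round(base_node[post])
          A <- cbind(1, vals[post, parents_ev, drop = FALSE])
          cf <- qr.coef(qr(A), tgt)
          cf[is.na(cf)] <- 0
          n <- length(parents_ev)
          aff <- c(cf[-1L], cf[1L])
          mdl <- gfis(rbind(aff, aff))
          post_models[[cond]] <- mdl
          pmin(pmax(evaluate_gfis(mdl, vals[post, parents_ev, drop = FALSE]),
                    0), 1)
        },
        flip = {
          cons <- consequents[[event$node]][[cond]]
          fl <- cbind(-cons[, -ncol(cons), drop = FALSE], 1 - cons[, ncol(cons)])
          post_models[[cond]] <- gfis(fl)
          1 - base_node[post]
        },
        constant_shift = {
          m <- mean(base_node[post])
          cv <- if (m <= 0.5) m + event$effect_size else m - event$effect_size
          cv <- min(max(cv, 0), 1)
          n <- length(topology_parents(topo, event$node))
          post_models[[cond]] <- gfis(rbind(c(rep(0, n), cv), c(rep(0, n), cv)))
          rep(cv, sum(post))
        },
        rewire = {
          mdl <- gfis(rewire_cons[[cond]])
          post_models[[cond]] <- mdl
          pmin(pmax(evaluate_gfis(mdl, vals[post, event$new_parent]), 0), 1)
        }
      )
      vals[post, event$node] <- post_y
      # propagate through descendants with their baseline models
      for (node in targets) {
        if (node == event$node) next
        parents <- topology_parents(topo, node)
        y <- evaluate_gfis(gfis(consequents[[node]][[cond]]),
                           vals[, parents, drop = FALSE])
        vals[, node] <- pmin(pmax(y, 0), 1)
      }
      event_vals[[cond]] <- vals
    }
    event_truth <- list(node = event$node, t_star = event$t_star,
                        type = event$type, new_parent = event$new_parent,
                        post_models = post_models)
  }

  melt <- function(vals_by_cond) {
    do.call(rbind, lapply(conds, function(cond) {
      v <- vals_by_cond[[cond]]
      data.frame(analyte = rep(colnames(v), each = length(times)),
                 condition = cond,
                 time_h = rep(times, times = ncol(v)),
                 value = as.vector(v), stringsAsFactors = FALSE)
    }))
  }
  base_df <- melt(base_vals)
  ord <- order(base_df$analyte, base_df$condition, base_df$time_h)
  base_df <- base_df[ord, , drop = FALSE]

  # stage 4: measurement noise; one draw per (analyte, condition, time) in
  # canonical order, hence identical with and without an event
  eps <- if (spec$noise_sigma > 0) {
    with_local_seed(seeds[4L], rnorm(nrow(base_df), 0, spec$noise_sigma))
  } else {
    numeric(nrow(base_df))
  }
  noisy <- function(df) {
    df$value <- pmin(pmax(df$value + eps, 0), 1)
    df
  }
  base_noisy <- noisy(base_df)

  # final max-scaling; factors always from the no-event baseline so an event
  # never changes pre-switch values
  key <- interaction(base_noisy$analyte, base_noisy$condition, drop = TRUE)
  mx <- ave(base_noisy$value, key, FUN = max)
  mx[mx == 0] <- 1

  out_df <- if (is.null(event)) base_noisy else noisy(melt(event_vals)[ord, , drop = FALSE])
  out_df$value <- pmin(out_df$value / mx, 1)
  rownames(out_df) <- NULL

  scale_factors <- unique(data.frame(analyte = base_noisy$analyte,
                                     condition = base_noisy$condition,
                                     scale = mx, stringsAsFactors = FALSE))
  structure(
    list(data = out_df,
         truth = list(spec = spec, input_params = input_params,
                      consequents = consequents, event = event_truth,
                      scale_factors = scale_factors)),
    class = "synthetic_dataset"
  )
}

#' Generate a synthetic raw (phospho + total) dataset
#'
#' Invents smooth, strictly positive total-protein intensity trajectories and
#' a per-condition intensity scale, then sets the phospho channel so that the
#' preprocessing pipeline recovers the scaled dataset:
#' `preprocess_dataset(generate_raw(spec)$data)` equals
#' `generate_scaled(spec)$data` up to floating-point rounding.
#'
#' @param spec a [generator_spec()].
#' @return a list of class `"synthetic_dataset"` with `data` (raw
#'   measurements: `analyte`, `condition`, `time_h`, `channel`, `value`) and
#'   the same `truth` as [generate_scaled()] plus the total-channel
#'   parameters.
#' @export
generate_raw <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  scaled <- generate_scaled(spec)
  seeds <- stage_seeds(spec$seed)
  d <- scaled$data
  tmax <- max(spec$times)
  series <- unique(d[, c("analyte", "condition")])
  total_params <- with_local_seed(seeds[5L], {
    tp <- vector("list", nrow(series))
    for (i in seq_len(nrow(series))) {
      tp[[i]] <- list(level = runif(1, 500, 5000), amp = runif(1, 0, 0.3),
                      freq = runif(1, 0.3, 1), phase = runif(1, 0, 2 * pi))
    }
    names(tp) <- paste(series$analyte, series$condition, sep = "\r")
    cond_scale <- setNames(runif(length(spec$conditions), 0.5, 2),
                           spec$conditions)
    list(series = tp, cond_scale = cond_scale)
  })
  key <- paste(d$analyte, d$condition, sep = "\r")
  total <- vapply(seq_len(nrow(d)), function(i) {
    p <- total_params$series[[key[i]]]
    p$level * (1 + p$amp * sin(2 * pi * p$freq * d$time_h[i] / tmax + p$phase))
  }, numeric(1))
  phospho <- d$value * total * total_params$cond_scale[d$condition]
  raw <- rbind(
    data.frame(analyte = d$analyte, condition = d$condition, time_h = d$time_h,
               channel = "phospho", value = phospho, stringsAsFactors = FALSE),
    data.frame(analyte = d$analyte, condition = d$condition, time_h = d$time_h,
               channel = "total", value = total, stringsAsFactors = FALSE)
  )
  rownames(raw) <- NULL
  truth <- scaled$truth
  truth$total_params <- total_params
  structure(list(data = raw, truth = truth), class = "synthetic_dataset")
}
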