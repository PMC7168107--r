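#' Simulation batch configuration
#'
#' Bundles the knobs of the fault-injection study design: exhaustive
#' single-fault scenarios over every faultable component plus
#' `instances_per_cardinality` random scenarios for each multi-fault
#' cardinality.  With the default 75-faultable model this yields
#' `75 + 150 * 5 = 825` instances before the shared-affecting-component
#' discard rule is applied.
#'
#' @param multi_fault_range integer interval of multi-fault cardinalities
#' @param fail_prob probability that an affected component is labeled as
#'   failing its test, in (0, 1]; `1` is the relaxed mode in which every
#'   affected component fails
#' @param singles_exhaustive generate one single-fault scenario per
#'   faultable component
#' @param instances_per_cardinality random scenarios per multi-fault
#'   cardinality
#' @param discard_mode `"resample"` (default) redraws entangled fault sets
#'   until disjoint, so the batch reaches its configured size, reporting
#'   the number of redraws; `"discard"` instead drops entangled scenarios
#'   after generation (reporting the count), mirroring a
#'   generate-then-filter study design
#' @param max_retries redraw budget per scenario in resample mode
#' @param seed integer seed for the whole batch
#' @return a list of class `sim_config`
#' @export
sim_config <- function(multi_fault_range = c(2L, 6L), fail_prob = 0.5,
                       singles_exhaustive = TRUE,
                       instances_per_cardinality = 150L,
                       discard_mode = c("resample", "discard"),
                       max_retries = 1000L, seed = 1L) {
  discard_mode <- match.arg(discard_mode)
  if (!(fail_prob > 0 && fail_prob <= 1)) {
    physdx_error("physdx_config_error", "fail_prob must lie in (0, 1]")
  }
  if (length(multi_fault_range) != 2 || multi_fault_range[1] > multi_fault_range[2] ||
      multi_fault_range[1] < 1) {
    physdx_error("physdx_config_error", "multi_fault_range must be a valid interval")
  }
  structure(list(multi_fault_range = as.integer(multi_fault_range),
                 fail_prob = fail_prob,
                 singles_exhaustive = isTRUE(singles_exhaustive),
                 instances_per_cardinality = as.integer(instances_per_cardinality),
                 discard_mode = discard_mode,
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Inject a random fault set
#'
#' Draws `k` distinct faultable components uniformly without replacement,
#' using the current RNG stream.  Dermatomes are never faultable.
#'
#' @param model an [anatomy_model()]
#' @param k number of faults
#' @return sorted character vector of component ids
#' @export
inject_faults <- function(model, k) {
  f <- faultable_components(model)
  if (k < 1 || k > length(f)) {
    physdx_error("physdx_config_error",
                 paste0("fault cardinality ", k, " out of range [1, ",
                        length(f), "]"))
  }
  sort(if (length(f) == 1) f else sample(f, k))
}

#' Do injected faults share an affecting component?
#'
#' True when two faults have overlapping self-inclusive ancestor
#' closures — either a common ancestor or one fault affecting the other.
#' Such fault sets are not jointly recoverable as a minimal diagnosis, so
#' batch generation screens them out.
#'
#' @inheritParams inject_faults
#' @param faults character vector of component ids
#' @return `TRUE` or `FALSE`
#' @export
has_shared_affecting_component <- function(model, faults) {
  if (length(faults) < 2) return(FALSE)
  closures <- lapply(faults, closure_up, model = model)
  for (i in seq_len(length(closures) - 1)) {
    for (j in seq(i + 1, length(closures))) {
      if (length(intersect(closures[[i]], closures[[j]]))) return(TRUE)
    }
  }
  FALSE
}

#' Simulate test labels for an injected fault set
#'
#' Components in `faults` or affected by them (their descendants) fail
#' their test with probability `fail_prob`; all other components pass.
#' Every fault is then guaranteed at least one explaining symptom: if no
#' component in a fault's self-inclusive descendant set is labeled as
#' failing, one member of that set is chosen uniformly and forced to fail.
#' Uses the current RNG stream.
#'
#' @inheritParams has_shared_affecting_component
#' @param fail_prob per-component failure-labeling probability in (0, 1]
#' @return named logical vector over all components (`TRUE` = test passes)
#' @export
label_symptoms <- function(model, faults, fail_prob = 0.5) {
  stopifnot(length(faults) >= 1)
  am_check_id(model, faults)
  ids <- component_ids(model)
  labels <- setNames(rep(TRUE, length(ids)), ids)
  affected <- unique(c(faults, unlist(model$descendants[faults], use.names = FALSE)))
  labels[affected] <- runif(length(affected)) >= fail_prob
  for (f in faults) {
    sf <- c(f, model$descendants[[f]])
    if (all(labels[sf])) {
      pick <- if (length(sf) > 1) sample(sf, 1) else sf
      labels[pick] <- FALSE
    }
  }
  labels
}

#' Draw the initial observation set from simulated labels
#'
#' The patient reports only some symptoms: the observation-set size is
#' drawn uniformly from 1 to `min(k, number of failing labels)` and that
#' many failing components are drawn uniformly without replacement, each
#' observed as `testOK = FALSE`.  Uses the current RNG stream.
#'
#' @param labels named logical label map from [label_symptoms()]
#' @param k the fault cardinality (upper bound on the observation size)
#' @return an [observation_set()] of failed observations
#' @export
select_observations <- function(labels, k) {
  falses <- names(labels)[!labels]
  if (!length(falses)) {
    physdx_error("physdx_contract_error", "no failing labels to observe")
  }
  smax <- min(k, length(falses))
  s <- if (smax == 1) 1L else sample.int(smax, 1)
  picks <- if (length(falses) == 1) falses else sample(falses, s)
  observation_set(picks, rep(FALSE, length(picks)))
}

#' Generate one ground-truth scenario
#'
#' Composes [inject_faults()] (redrawing fault sets that share an
#' affecting component when `resample_shared` is on),
#' [label_symptoms()] and [select_observations()] into a complete seeded
#' scenario: the injected "real diagnosis", the full simulated label map
#' that stands in for the clinician's answers during troubleshooting, and
#' the initial observation subset.
#'
#' @inheritParams label_symptoms
#' @param k fault cardinality
#' @param seed integer seed; `NULL` uses the current RNG stream
#' @param faults optional fixed fault set (used for the exhaustive
#'   single-fault scenarios); skips injection
#' @param resample_shared redraw entangled fault sets (see
#'   [has_shared_affecting_component()])
#' @param max_retries redraw budget before giving up
#' @return an object of class `gt_scenario`: list with `faults`, `labels`,
#'   `initial_obs`, `k`, `fail_prob`, `seed`
#' @export
generate_scenario <- function(model, k, fail_prob = 0.5, seed = NULL,
                              faults = NULL, resample_shared = TRUE,
                              max_retries = 1000L) {
  stopifnot(inherits(model, "anatomy_model"))
  with_seed(seed, {
    tries <- 0L
    if (is.null(faults)) {
      faults <- inject_faults(model, k)
      if (resample_shared) {
        while (has_shared_affecting_component(model, faults)) {
          tries <- tries + 1L
          if (tries > max_retries) {
            physdx_error("physdx_generation_error",
                         paste0("could not draw ", k,
                                " ancestor-disjoint faults in ",
                                max_retries, " retries"))
          }
          faults <- inject_faults(model, k)
        }
      }
    } else {
      am_check_id(model, faults)
      k <- length(faults)
    }
    labels <- label_symptoms(model, faults, fail_prob)
    obs <- select_observations(labels, k)
    structure(list(faults = faults, labels = labels, initial_obs = obs,
                   k = k, fail_prob = fail_prob, seed = seed),
              class = "gt_scenario", n_redraws = tries)
  })
}

#' @export
print.gt_scenario <- function(x, ...) {
  cat("Ground-truth scenario (k = ", x$k, ", fail_prob = ", x$fail_prob,
      ")\n", sep = "")
  cat("  faults:  ", paste(x$faults, collapse = ", "), "\n", sep = "")
  cat("  symptoms:", sum(!x$labels), "failing labels;",
      length(x$initial_obs), "initially observed\n")
  invisible(x)
}

#' Generate a batch of scenarios
#'
#' Applies a [sim_config()] to a model: optional exhaustive single-fault
#' scenarios (one per faultable component) plus
#' `instances_per_cardinality` scenarios per multi-fault cardinality.
#' Fault sets sharing an affecting component are either discarded after
#' generation (`discard_mode = "discard"`, mirroring the study design
#' where discards are counted) or redrawn (`"resample"`).
#'
#' @inheritParams inject_faults
#' @param config a [sim_config()]
#' @return an object of class `sim_batch`: list with `scenarios` (list of
#'   `gt_scenario`) and `manifest` (config echo plus `n_pre_discard` — the
#'   configured number of instances before any filtering —, `n_discarded`
#'   — dropped scenarios in discard mode, fault-set redraws in resample
#'   mode — and `n_kept`)
#' @export
generate_batch <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "anatomy_model"), inherits(config, "sim_config"))
  f <- faultable_components(model)
  if (config$multi_fault_range[2] > length(f)) {
    physdx_error("physdx_config_error",
                 "multi-fault cardinality exceeds the number of faultable components")
  }
  with_seed(config$seed, {
    scenarios <- list()
    n_pre <- 0L
    n_disc <- 0L
    draw_seed <- function() sample.int(.Machine$integer.max, 1)
    if (config$singles_exhaustive) {
      for (comp in f) {
        n_pre <- n_pre + 1L
        scenarios[[length(scenarios) + 1]] <-
          generate_scenario(model, 1L, config$fail_prob, seed = draw_seed(),
                            faults = comp)
      }
    }
    for (k in seq(config$multi_fault_range[1], config$multi_fault_range[2])) {
      for (i in seq_len(config$instances_per_cardinality)) {
        n_pre <- n_pre + 1L
        if (config$discard_mode == "discard") {
          sc <- generate_scenario(model, k, config$fail_prob,
                                  seed = draw_seed(), resample_shared = FALSE)
          if (has_shared_affecting_component(model, sc$faults)) {
            n_disc <- n_disc + 1L
          } else {
            scenarios[[length(scenarios) + 1]] <- sc
          }
        } else {
          sc <- generate_scenario(model, k, config$fail_prob,
                                  seed = draw_seed(), resample_shared = TRUE,
                                  max_retries = config$max_retries)
          n_disc <- n_disc + attr(sc, "n_redraws")
          scenarios[[length(scenarios) + 1]] <- sc
        }
      }
    }
    structure(list(scenarios = scenarios,
                   manifest = c(unclass(config),
                                list(n_pre_discard = n_pre,
                                     n_discarded = n_disc,
                                     n_kept = length(scenarios)))),
              class = "sim_batch")
  })
}

#' @export
print.sim_batch <- function(x, ...) {
  m <- x$manifest
  cat("Scenario batch:", m$n_kept, "scenarios kept of", m$n_pre_discard,
      "generated (", m$n_discarded, "discarded: shared affecting component)\n")
  cat("  fail_prob:", m$fail_prob, " discard mode:", m$discard_mode,
      " seed:", m$seed, "\n")
  invisible(x)
}

#' Answer oracle backed by a scenario's label map
#'
#' Returns a deterministic function `component id -> logical` answering
#' probes from the scenario's simulated labels; components outside the
#' label map (none, by construction) answer `TRUE`.
#'
#' @param scenario a `gt_scenario`
#' @return a function usable as the `oracle` of [run_probing()]
#' @export
oracle_from_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "gt_scenario"))
  labels <- scenario$labels
  function(comp) {
    v <- labels[comp]
    if (is.na(v)) TRUE else unname(v)
  }
}

#' Write scenarios as JSON lines
#' @param batch a `sim_batch` or plain list of `gt_scenario`
#' @param path output `.jsonl` path (one scenario per line)
#' @param manifest_path optional path for the batch manifest JSON
#' @return `path`, invisibly
#' @export
write_scenarios <- function(batch, path, manifest_path = NULL) {
  scenarios <- if (inherits(batch, "sim_batch")) batch$scenarios else batch
  lines <- vapply(scenarios, function(sc) {
    jsonlite::toJSON(list(
      faults = sc$faults,
      labels = as.list(sc$labels),
      initial_obs = as.list(unclass(sc$initial_obs)),
      k = sc$k, fail_prob = sc$fail_prob,
      seed = if (is.null(sc$seed)) NA else sc$seed
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  if (!is.null(manifest_path) && inherits(batch, "sim_batch")) {
    jsonlite::write_json(batch$manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read scenarios from JSON lines
#' @param path a `.jsonl` file written by [write_scenarios()]
#' @return list of `gt_scenario`
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) {
    physdx_error("physdx_io_error", paste0("scenario file not found: ", path))
  }
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line)
    structure(list(
      faults = as.character(x$faults),
      labels = unlist(x$labels),
      initial_obs = observation_set(names(x$initial_obs),
                                    unlist(x$initial_obs, use.names = FALSE)),
      k = x$k, fail_prob = x$fail_prob,
      seed = if (is.null(x$seed) || is.na(x$seed)) NULL else x$seed
    ), class = "gt_scenario")
  })
}
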