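# Shared fixtures and independent oracles for the test suite.
# The oracles deliberately avoid the package's graph code paths: reachability
# is recomputed from the raw edge list by fixed-point adjacency expansion and
# diagnoses by exhaustive subset enumeration, so they can arbitrate.

toy_chain <- function() {
  # R1 -> N1 -> M1, N1 -> D1
  anatomy_model(
    data.frame(id = c("R1", "N1", "M1", "D1"),
               kind = c("nerve_root", "nerve", "muscle", "dermatome")),
    data.frame(source = c("R1", "N1", "N1"),
               target = c("N1", "M1", "D1")))
}

toy_diamond <- function() {
  # R1 -> {N1, N2} -> M1
  anatomy_model(
    data.frame(id = c("R1", "N1", "N2", "M1"),
               kind = c("nerve_root", "nerve", "nerve", "muscle")),
    data.frame(source = c("R1", "R1", "N1", "N2"),
               target = c("N1", "N2", "M1", "M1")))
}

# Transitive ancestor sets via boolean fixed point on the adjacency matrix.
brute_ancestors <- function(model) {
  ids <- model$components$id
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(model$edges)) {
    adj[cbind(model$edges$source, model$edges$target)] <- TRUE
  }
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  lapply(setNames(ids, ids), function(id) ids[reach[, id]])
}

# Is `delta` consistent with the observations under the weak fault model?
# Forced-pass propagation: a component's test is provably passing iff the
# component and its entire ancestor closure are healthy; a failed observation
# of such a component is a contradiction.
brute_is_diagnosis <- function(model, obs, delta, anc = brute_ancestors(model)) {
  failed <- names(obs)[!obs]
  for (c in failed) {
    closure <- c(c, anc[[c]])
    if (!any(closure %in% delta)) return(FALSE)
  }
  TRUE
}

# All subset-minimal diagnoses by exhaustive subset scan over the faultable
# components (feasible up to ~12 faultable components).
brute_min_diagnoses <- function(model, obs) {
  f <- sort(faultable_components(model))
  anc <- brute_ancestors(model)
  subsets <- list()
  for (sz in 0:length(f)) {
    idx <- if (sz == 0) list(integer(0)) else
      asplit(utils::combn(length(f), sz), 2)
    for (s in idx) {
      delta <- f[unlist(s)]
      if (!brute_is_diagnosis(model, obs, delta, anc)) next
      # minimal iff no previously found (smaller) diagnosis is a subset
      if (!any(vapply(subsets, function(d) all(d %in% delta), logical(1)))) {
        subsets[[length(subsets) + 1]] <- delta
      }
    }
  }
  subsets
}

canon_sets <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), character(1)))
}

# Small random model for oracle-equivalence sweeps (<= 12 faultable comps).
small_random_model <- function(seed) {
  set.seed(seed)
  generate_synthetic_model(
    n_roots = sample(2:3, 1), n_nerves = sample(2:4, 1),
    n_muscles = sample(3:5, 1), n_dermatomes = sample(1:3, 1),
    edges_per_node = sample(c(1.2, 1.5, 2), 1), seed = seed + 1000L)
}

# Random observation pattern biased towards failures on sinks.
random_obs <- function(model, seed) {
  set.seed(seed)
  ids <- component_ids(model)
  n <- sample.int(min(5, length(ids)), 1)
  picked <- sample(ids, n)
  observation_set(picked, runif(n) < 0.4)
}
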