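#' @importFrom stats rpois runif setNames aggregate
#' @importFrom utils head write.csv
NULL

COMPONENT_KINDS <- c("nerve_root", "nerve", "muscle", "dermatome")

# Kinds that may be announced faulty.  Dermatomes are test surfaces only:
# a defected skin sensation implicates the innervating nerves/roots, never
# the dermatome itself, which is assumed healthy.
FAULTABLE_KINDS <- c("nerve_root", "nerve", "muscle")

# Evaluate `expr` under a private RNG stream started from `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

physdx_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "physdx_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Build an anatomical influence model
#'
#' Constructs and validates a typed influence DAG over four kinds of
#' anatomical components: nerve roots, nerves, muscles and dermatomes.
#' An edge `source -> target` states that the output of `source` is an
#' input of `target`, so a fault in `source` can mask or defeat any test
#' of `target`.
#'
#' Model invariants: all component ids are unique and non-empty, every edge
#' references known components and the graph is acyclic; nerve roots are
#' sources (no incoming edges) and muscles and dermatomes are sinks (no
#' outgoing edges).  Violations raise an error listing every problem; use
#' [validate_anatomy()] to obtain the list without an error.
#'
#' @param components data frame with columns `id`, `name`, `kind`
#'   (`kind` one of `"nerve_root"`, `"nerve"`, `"muscle"`, `"dermatome"`).
#'   A missing `name` column is filled from `id`.
#' @param edges data frame with columns `source`, `target` (component ids);
#'   may have zero rows.
#' @return An object of class `anatomy_model` with precomputed transitive
#'   ancestor/descendant closures.
#' @seealso [load_model()], [fragment_model()], [generate_synthetic_model()]
#' @export
anatomy_model <- function(components, edges = NULL) {
  raw <- am_coerce(components, edges)
  problems <- validate_anatomy(raw)
  if (length(problems)) {
    physdx_error("physdx_validation_error",
                 paste0("invalid anatomy model:\n",
                        paste0("  - ", problems, collapse = "\n")),
                 problems = problems)
  }
  am_finalize(raw)
}

am_coerce <- function(components, edges) {
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  if (is.null(components$name)) components$name <- components$id
  components <- components[, c("id", "name", "kind")]
  components$id <- as.character(components$id)
  components$kind <- as.character(components$kind)
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0)) {
    edges <- data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)[, c("source", "target")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  list(components = components, edges = edges)
}

#' List invariant violations of an anatomy model
#'
#' @param x an `anatomy_model`, or a list with `components` and `edges`
#'   data frames (as produced while loading an untrusted file).
#' @return Character vector of human-readable violation descriptions;
#'   empty when the model is valid.
#' @export
validate_anatomy <- function(x) {
  if (inherits(x, "anatomy_model")) {
    raw <- list(components = x$components, edges = x$edges)
  } else {
    raw <- am_coerce(x$components, x$edges)
  }
  comps <- raw$components
  edges <- raw$edges
  problems <- character()

  if (nrow(comps) == 0) {
    return("model has no components")
  }
  if (any(!nzchar(comps$id) | is.na(comps$id))) {
    problems <- c(problems, "component ids must be non-empty strings")
  }
  dup <- unique(comps$id[duplicated(comps$id)])
  if (length(dup)) {
    problems <- c(problems,
                  paste0("duplicated component id(s): ", paste(dup, collapse = ", ")))
  }
  bad_kind <- unique(comps$kind[!comps$kind %in% COMPONENT_KINDS])
  if (length(bad_kind)) {
    problems <- c(problems,
                  paste0("unknown component kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  ids <- comps$id
  kind <- setNames(comps$kind, ids)

  missing_ref <- unique(c(edges$source[!edges$source %in% ids],
                          edges$target[!edges$target %in% ids]))
  if (length(missing_ref)) {
    problems <- c(problems,
                  paste0("edge references unknown component(s): ",
                         paste(missing_ref, collapse = ", ")))
  }
  self <- edges$source == edges$target
  if (any(self)) {
    problems <- c(problems,
                  paste0("self-loop edge on: ",
                         paste(unique(edges$source[self]), collapse = ", ")))
  }

  # Remaining checks need a well-formed edge list.
  if (length(missing_ref) || length(dup) || length(bad_kind)) {
    return(problems)
  }

  sink_out <- edges$source[kind[edges$source] %in% c("muscle", "dermatome")]
  if (length(sink_out)) {
    problems <- c(problems,
                  paste0("muscles/dermatomes are sinks but have outgoing edge(s): ",
                         paste(unique(sink_out), collapse = ", ")))
  }
  root_in <- edges$target[kind[edges$target] == "nerve_root"]
  if (length(root_in)) {
    problems <- c(problems,
                  paste0("nerve roots are sources but have incoming edge(s): ",
                         paste(unique(root_in), collapse = ", ")))
  }

  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = ids)
  if (!igraph::is_dag(g)) {
    sc <- igraph::components(g, mode = "strong")
    cyc <- names(sc$membership)[sc$membership %in% which(sc$csize > 1)]
    problems <- c(problems,
                  paste0("influence graph contains a cycle through: ",
                         paste(sort(cyc), collapse = ", ")))
  }
  problems
}

am_finalize <- function(raw) {
  comps <- raw$components
  edges <- raw$edges
  ids <- comps$id
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = ids)
  anc <- lapply(ids, function(id) {
    setdiff(names(igraph::subcomponent(g, id, mode = "in")), id)
  })
  des <- lapply(ids, function(id) {
    setdiff(names(igraph::subcomponent(g, id, mode = "out")), id)
  })
  names(anc) <- ids
  names(des) <- ids
  kind <- setNames(comps$kind, ids)
  structure(
    list(components = comps, edges = edges, kind = kind,
         ancestors = anc, descendants = des,
         faultable = ids[kind %in% FAULTABLE_KINDS],
         dermatomes = ids[kind == "dermatome"]),
    class = "anatomy_model"
  )
}

am_check_id <- function(model, id) {
  missing <- setdiff(id, model$components$id)
  if (length(missing)) {
    physdx_error("physdx_lookup_error",
                 paste0("unknown component id(s): ", paste(missing, collapse = ", ")))
  }
  invisible(id)
}

#' Transitive ancestors of a component
#'
#' All components with a directed influence path *to* `id` (excluding `id`
#' itself): the components whose fault could explain a failed test of `id`.
#'
#' @param model an `anatomy_model`
#' @param id a component id
#' @return character vector of component ids
#' @export
ancestors <- function(model, id) {
  stopifnot(inherits(model, "anatomy_model"))
  am_check_id(model, id)
  model$ancestors[[id]]
}

#' Transitive descendants of a component
#'
#' All components reachable from `id` (excluding `id` itself): the
#' components whose tests can be affected by a fault in `id`.
#'
#' @inheritParams ancestors
#' @return character vector of component ids
#' @export
descendants <- function(model, id) {
  stopifnot(inherits(model, "anatomy_model"))
  am_check_id(model, id)
  model$descendants[[id]]
}

# Self-inclusive ancestor closure: the set implicated by a failed test of id.
closure_up <- function(model, id) c(id, model$ancestors[[id]])

#' Component ids of a model
#' @inheritParams ancestors
#' @return character vector of all component ids
#' @export
component_ids <- function(model) model$components$id

#' Faultable components of a model
#'
#' Nerve roots, nerves and muscles; dermatomes are assumed healthy and are
#' excluded.
#' @inheritParams ancestors
#' @return character vector of component ids
#' @export
faultable_components <- function(model) model$faultable

#' @export
print.anatomy_model <- function(x, ...) {
  tab <- table(factor(x$kind, levels = COMPONENT_KINDS))
  cat("Anatomical influence model:", nrow(x$components), "components,",
      nrow(x$edges), "edges\n")
  cat(sprintf("  %s: %d\n", names(tab), as.integer(tab)), sep = "")
  invisible(x)
}

#' @export
plot.anatomy_model <- function(x, ...) {
  g <- igraph::graph_from_data_frame(x$edges, directed = TRUE,
                                     vertices = x$components$id)
  pal <- c(nerve_root = "#d95f02", nerve = "#7570b3",
           muscle = "#1b9e77", dermatome = "#e7298a")
  igraph::plot.igraph(
    g, vertex.color = pal[x$kind[igraph::V(g)$name]],
    vertex.label.cex = 0.7, edge.arrow.size = 0.3,
    layout = igraph::layout_with_sugiyama(g)$layout, ...)
  invisible(x)
}

#' Load an anatomy model from JSON
#'
#' Expected dialect:
#' `{"components": [{"id", "name", "kind"}, ...], "edges": [{"source", "target"}, ...]}`.
#'
#' @param path path to a model JSON file
#' @return a validated [anatomy_model()]
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    physdx_error("physdx_io_error", paste0("model file not found: ", path))
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      physdx_error("physdx_parse_error",
                   paste0("malformed model file '", path, "': ", conditionMessage(e)))
    })
  if (!is.list(parsed) || is.null(parsed$components)) {
    physdx_error("physdx_parse_error",
                 paste0("malformed model file '", path,
                        "': missing 'components' field"))
  }
  anatomy_model(parsed$components, parsed$edges)
}

#' Write an anatomy model to JSON
#' @param model an `anatomy_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "anatomy_model"))
  jsonlite::write_json(
    list(components = model$components, edges = model$edges),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export the influence graph in DOT format
#'
#' One node per component, colored by kind; suitable for Graphviz
#' inspection of the model structure.
#'
#' @inheritParams write_model
#' @return `path`, invisibly
#' @export
export_dot <- function(model, path) {
  stopifnot(inherits(model, "anatomy_model"))
  pal <- c(nerve_root = "orange", nerve = "slateblue",
           muscle = "seagreen", dermatome = "pink")
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  nodes <- sprintf('  %s [label=%s, style=filled, fillcolor=%s];',
                   q(model$components$id), q(model$components$name),
                   pal[model$components$kind])
  edges <- sprintf('  %s -> %s;', q(model$edges$source), q(model$edges$target))
  writeLines(c("digraph anatomy {", "  rankdir=TB;", nodes, edges, "}"), path)
  invisible(path)
}

#' Hand-encoded fragment of the upper-limb innervation model
#'
#' A seven-component fragment around the C6 nerve root: C6 innervates the
#' radial and median nerves; the radial nerve serves the deltoid and
#' extensor carpi ulnaris muscles and the DC6 dermatome (thumb sensation);
#' the median nerve serves the brachialis.  Small enough to trace
#' diagnoses by hand, rich enough to exercise masking: a failed shoulder
#' extension (Deltoid) implicates the deltoid itself, the radial nerve or
#' the C6 root.
#'
#' @return an `anatomy_model` with components C6, Radial, Median, Deltoid,
#'   ExtensorCarpiUlnaris, Brachialis and DC6
#' @export
fragment_model <- function() {
  components <- data.frame(
    id = c("C6", "Radial", "Median", "Deltoid",
           "ExtensorCarpiUlnaris", "Brachialis", "DC6"),
    name = c("Nerve root C6", "Radial nerve", "Median nerve",
             "Deltoid muscle", "Extensor carpi ulnaris muscle",
             "Brachialis muscle", "Dermatome DC6 (thumb)"),
    kind = c("nerve_root", "nerve", "nerve", "muscle",
             "muscle", "muscle", "dermatome"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("C6", "C6", "Radial", "Radial", "Median", "Radial"),
    target = c("Radial", "Median", "Deltoid", "ExtensorCarpiUlnaris",
               "Brachialis", "DC6"),
    stringsAsFactors = FALSE)
  anatomy_model(components, edges)
}

#' Generate a random layered anatomy model
#'
#' Emulates the layered structure of a clinical upper-body model: nerve
#' roots innervate nerves, nerves serve muscles and dermatomes.  Every
#' non-root component receives at least one parent; additional parents are
#' drawn so that the mean in-degree of non-root components is about
#' `edges_per_node`, which creates the overlapping influence closures that
#' make diagnosis ambiguous.  The default sizes total 75 components, with
#' enough distinct root lineages that multi-fault scenarios with pairwise
#' disjoint ancestor closures remain reasonably common up to six faults
#' (see [has_shared_affecting_component()]).
#'
#' @param n_roots,n_nerves,n_muscles,n_dermatomes layer sizes (all >= 1)
#' @param edges_per_node target mean number of parents per non-root
#'   component (>= 1)
#' @param seed integer seed; the model is a deterministic function of the
#'   arguments
#' @param root_dermatome_edges allow direct nerve_root -> dermatome edges
#' @param root_muscle_edges allow direct nerve_root -> muscle edges
#' @return a validated `anatomy_model`
#' @export
generate_synthetic_model <- function(n_roots = 12, n_nerves = 24,
                                     n_muscles = 28, n_dermatomes = 11,
                                     edges_per_node = 1.5, seed = 1L,
                                     root_dermatome_edges = TRUE,
                                     root_muscle_edges = FALSE) {
  if (any(c(n_roots, n_nerves, n_muscles, n_dermatomes) < 1)) {
    physdx_error("physdx_config_error", "all layer sizes must be >= 1")
  }
  if (edges_per_node < 1) {
    physdx_error("physdx_config_error", "edges_per_node must be >= 1")
  }
  roots <- sprintf("R%02d", seq_len(n_roots))
  nerves <- sprintf("N%02d", seq_len(n_nerves))
  muscles <- sprintf("M%02d", seq_len(n_muscles))
  derms <- sprintf("D%02d", seq_len(n_dermatomes))

  with_seed(seed, {
    draw_parents <- function(pool) {
      n <- min(length(pool), 1 + rpois(1, edges_per_node - 1))
      if (length(pool) == 1) pool else sample(pool, n)
    }
    edges <- list()
    for (n in nerves) {
      edges[[length(edges) + 1]] <- data.frame(source = draw_parents(roots),
                                               target = n)
    }
    muscle_pool <- c(nerves, if (root_muscle_edges) roots)
    for (m in muscles) {
      edges[[length(edges) + 1]] <- data.frame(source = draw_parents(muscle_pool),
                                               target = m)
    }
    derm_pool <- c(nerves, if (root_dermatome_edges) roots)
    for (d in derms) {
      edges[[length(edges) + 1]] <- data.frame(source = draw_parents(derm_pool),
                                               target = d)
    }
    edges <- do.call(rbind, edges)
  })

  components <- data.frame(
    id = c(roots, nerves, muscles, derms),
    name = c(paste("Nerve root", roots), paste("Nerve", nerves),
             paste("Muscle", muscles), paste("Dermatome", derms)),
    kind = rep(COMPONENT_KINDS, c(n_roots, n_nerves, n_muscles, n_dermatomes)),
    stringsAsFactors = FALSE)
  anatomy_model(components, edges)
}
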