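#' Compute conflict sets from failed tests
#'
#' Under the weak fault model a failed test of component `c` proves that
#' `c` or one of its ancestors in the influence graph is faulty; a passed
#' test proves nothing.  Each failed observation therefore yields one
#' conflict: its self-inclusive ancestor closure with dermatomes removed
#' (dermatomes are assumed healthy).  Duplicate conflicts and conflicts
#' that are supersets of other conflicts are dropped, as they are
#' logically redundant for the hitting-set computation.
#'
#' @param model an [anatomy_model()]
#' @param obs an [observation_set()] (or named logical vector / data frame
#'   coercible to one)
#' @return list of conflicts; each is a list with `members` (sorted
#'   character vector of faultable component ids) and `origin` (the failed
#'   test that generated it)
#' @export
compute_conflicts <- function(model, obs) {
  stopifnot(inherits(model, "anatomy_model"))
  obs <- as_observation_set(obs, model)
  failed <- names(obs)[!obs]
  conflicts <- lapply(failed, function(c) {
    members <- sort(setdiff(closure_up(model, c), model$dermatomes))
    if (!length(members)) {
      physdx_error("physdx_model_inconsistency",
                   paste0("failed test of '", c,
                          "' implicates no faultable component"))
    }
    list(members = members, origin = c)
  })
  # drop duplicates, then conflicts subsuming (strictly containing) others
  keys <- vapply(conflicts, function(cf) paste(cf$members, collapse = "\r"),
                 character(1))
  conflicts <- conflicts[!duplicated(keys)]
  sets <- lapply(conflicts, `[[`, "members")
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      i != j && length(sets[[j]]) < length(sets[[i]]) &&
        all(sets[[j]] %in% sets[[i]])
    }, logical(1)))
  }, logical(1))
  conflicts[keep]
}

#' Subset-minimal hitting sets of a conflict collection
#'
#' A hitting set intersects every conflict; the subset-minimal hitting
#' sets of the conflicts are exactly the subset-minimal diagnoses.
#' Enumeration uses a hitting-set tree that branches on the elements of
#' the first conflict not yet hit, followed by an exact minimality filter
#' (a hitting set is minimal iff each of its elements hits some conflict
#' that no other element hits).
#'
#' @param conflicts list of conflicts as returned by [compute_conflicts()],
#'   or a plain list of character vectors
#' @return list of character vectors, sorted by size then lexicographically;
#'   `list(character(0))` when there are no conflicts (the empty diagnosis)
#' @export
minimal_hitting_sets <- function(conflicts) {
  sets <- lapply(conflicts, function(cf) {
    if (is.list(cf)) cf$members else cf
  })
  if (!length(sets)) return(list(character(0)))
  universe <- sort(unique(unlist(sets)))
  sets_i <- lapply(sets, function(s) match(s, universe))
  sets_i <- sets_i[order(lengths(sets_i))]

  acc <- new.env(parent = emptyenv())
  rec <- function(remaining, partial) {
    # drop conflicts already hit
    if (length(partial)) {
      remaining <- remaining[!vapply(remaining, function(s) {
        any(s %in% partial)
      }, logical(1))]
    }
    if (!length(remaining)) {
      key <- paste(sort(partial), collapse = ",")
      if (is.null(acc[[key]])) acc[[key]] <- sort(partial)
      return(invisible(NULL))
    }
    for (e in remaining[[1]]) rec(remaining[-1], c(partial, e))
    invisible(NULL)
  }
  rec(sets_i, integer(0))

  cands <- as.list(acc)
  minimal <- vapply(cands, function(s) {
    all(vapply(s, function(e) {
      any(vapply(sets_i, function(cf) {
        length(intersect(cf, s)) == 1L && e %in% cf
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  cands <- unname(cands[minimal])
  out <- lapply(cands, function(s) universe[s])
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out[order(lengths(out), keys)]
}

#' Diagnose an observation set
#'
#' The central inference step: failed tests are turned into conflicts
#' ([compute_conflicts()]), the subset-minimal hitting sets of the
#' conflicts are the candidate diagnoses ([minimal_hitting_sets()]), and
#' each diagnosis `delta` receives probability proportional to
#' `prior^|delta|` (components fail independently with a uniform prior
#' fault probability), normalized over the returned set.  With no failed
#' observations the single empty diagnosis (all healthy) is returned with
#' probability 1.
#'
#' @inheritParams compute_conflicts
#' @param prior prior fault probability of a single component, in (0, 1).
#'   Values below 0.5 rank smaller diagnoses higher.
#' @return an object of class `diagnosis_set`: a list with `diagnoses`
#'   (list of character vectors, decreasing probability), `prob`
#'   (normalized probabilities), `prior`, `model` and `obs`
#' @examples
#' m <- fragment_model()
#' d <- diagnose(m, observation_set("DC6", FALSE))
#' d                     # {C6} and {Radial}, each probability 0.5
#' health_state(d)
#' @export
diagnose <- function(model, obs, prior = 0.1) {
  stopifnot(inherits(model, "anatomy_model"))
  if (!(prior > 0 && prior < 1)) {
    physdx_error("physdx_config_error", "prior must lie strictly in (0, 1)")
  }
  obs <- as_observation_set(obs, model)
  hs <- minimal_hitting_sets(compute_conflicts(model, obs))
  new_diagnosis_set(hs, model, obs, prior)
}

new_diagnosis_set <- function(diagnoses, model, obs, prior) {
  w <- prior^lengths(diagnoses)
  p <- w / sum(w)
  keys <- vapply(diagnoses, paste, character(1), collapse = "\r")
  ord <- order(-p, lengths(diagnoses), keys)
  diagnoses <- diagnoses[ord]
  p <- p[ord]
  fcomp <- model$faultable
  inc <- matrix(FALSE, nrow = length(diagnoses), ncol = length(fcomp),
                dimnames = list(NULL, fcomp))
  flat <- unlist(diagnoses, use.names = FALSE)
  if (length(flat)) {
    inc[cbind(rep(seq_along(diagnoses), lengths(diagnoses)),
              match(flat, fcomp))] <- TRUE
  }
  structure(list(diagnoses = diagnoses, prob = p, prior = prior,
                 model = model, obs = obs, inc = inc),
            class = "diagnosis_set")
}

#' Check whether a fault set is a diagnosis
#'
#' A set `delta` is a diagnosis when assuming exactly the components in
#' `delta` faulty is consistent with the observations: every failed test
#' must be explainable, i.e. its self-inclusive ancestor closure must
#' contain a member of `delta`.  Passed tests impose nothing under the
#' weak fault model, so they never disqualify a candidate.
#'
#' @inheritParams compute_conflicts
#' @param delta character vector of faultable component ids (may be empty)
#' @return `TRUE` or `FALSE`
#' @export
is_diagnosis <- function(model, obs, delta) {
  stopifnot(inherits(model, "anatomy_model"))
  obs <- as_observation_set(obs, model)
  am_check_id(model, delta)
  if (any(delta %in% model$dermatomes)) {
    physdx_error("physdx_validation_error",
                 "delta may not contain dermatomes (assumed healthy)")
  }
  failed <- names(obs)[!obs]
  all(vapply(failed, function(c) {
    any(closure_up(model, c) %in% delta)
  }, logical(1)))
}

#' Per-component health state of a diagnosis set
#'
#' The health state of a component is the probability that it is faulty:
#' the total probability mass of the diagnoses containing it,
#' `H(c) = sum over delta containing c of P(delta)`.  Components appearing
#' in no diagnosis (including all dermatomes) have health state 0.
#'
#' @param D a `diagnosis_set`
#' @return named numeric vector over all components of the model
#' @export
health_state <- function(D) {
  stopifnot(inherits(D, "diagnosis_set"))
  h_f <- colSums(D$inc * D$prob)
  h <- setNames(numeric(nrow(D$model$components)), D$model$components$id)
  h[names(h_f)] <- h_f
  h
}

#' @export
print.diagnosis_set <- function(x, n = 10, ...) {
  k <- length(x$diagnoses)
  cat("Diagnosis set:", k, if (k == 1) "candidate" else "candidates",
      sprintf("(prior fault probability %g)\n", x$prior))
  shown <- head(seq_len(k), n)
  for (i in shown) {
    d <- x$diagnoses[[i]]
    cat(sprintf("  %5.3f  {%s}\n", x$prob[i],
                paste(d, collapse = ", ")))
  }
  if (k > length(shown)) cat("  ... and", k - length(shown), "more\n")
  invisible(x)
}

#' @export
summary.diagnosis_set <- function(object, ...) {
  h <- health_state(object)
  structure(list(
    n_diagnoses = length(object$diagnoses),
    entropy_bits = diagnosis_entropy(object),
    cardinality = table(lengths(object$diagnoses)),
    top_health = sort(h[h > 0], decreasing = TRUE)
  ), class = "summary.diagnosis_set")
}

#' @export
print.summary.diagnosis_set <- function(x, ...) {
  cat("Diagnoses:", x$n_diagnoses,
      sprintf("  entropy: %.3f bits\n", x$entropy_bits))
  cat("Cardinality distribution:\n")
  print(x$cardinality)
  cat("Most suspect components (health state):\n")
  print(round(head(x$top_health, 10), 3))
  invisible(x)
}

#' @export
plot.diagnosis_set <- function(x, ...) {
  h <- health_state(x)
  h <- h[x$model$faultable]
  h <- sort(h[h > 0], decreasing = TRUE)
  if (!length(h)) {
    graphics::barplot(0, names.arg = "(all healthy)", ylim = c(0, 1),
                      ylab = "health state")
    return(invisible(x))
  }
  graphics::barplot(h, las = 2, ylab = "health state P(faulty)",
                    ylim = c(0, 1), cex.names = 0.7, ...)
  invisible(x)
}

#' Write a diagnosis set to JSON and its health state to CSV
#'
#' @param D a `diagnosis_set`
#' @param json_path output path for the diagnosis list (sorted by
#'   decreasing probability); `NULL` to skip
#' @param csv_path output path for the `component,kind,health_state` table;
#'   `NULL` to skip
#' @return `D`, invisibly
#' @export
write_diagnoses <- function(D, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(D, "diagnosis_set"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      lapply(seq_along(D$diagnoses), function(i) {
        list(components = D$diagnoses[[i]], probability = D$prob[i])
      }),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    h <- health_state(D)
    write.csv(data.frame(component = names(h),
                         kind = unname(D$model$kind[names(h)]),
                         health_state = unname(h)),
              csv_path, row.names = FALSE)
  }
  invisible(D)
}
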