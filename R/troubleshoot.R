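#' Entropy of a diagnosis-set distribution
#'
#' Shannon entropy, in bits, of the normalized probabilities of the
#' candidate diagnoses: `-sum P(delta) * log2 P(delta)`.  A singleton set
#' has entropy 0; zero-probability terms contribute 0.
#'
#' @param D a `diagnosis_set`
#' @return entropy in bits
#' @export
diagnosis_entropy <- function(D) {
  stopifnot(inherits(D, "diagnosis_set"))
  p <- D$prob
  if (!length(p)) {
    physdx_error("physdx_empty_set", "entropy of an empty diagnosis set is undefined")
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Candidate probes for a diagnosis set
#'
#' The components worth testing next: the union of the members of all
#' candidate diagnoses, minus components already tested.
#'
#' @param D a `diagnosis_set`
#' @param already_tested character vector of component ids
#' @return sorted character vector of component ids
#' @export
candidate_probes <- function(D, already_tested = character()) {
  stopifnot(inherits(D, "diagnosis_set"))
  setdiff(sort(unique(unlist(D$diagnoses))), already_tested)
}

# Logical mask over the diagnoses: which survive a FAILED test of `comp`
# (those intersecting the self-inclusive ancestor closure of comp).
fail_survivors <- function(D, comp) {
  cl <- intersect(closure_up(D$model, comp), colnames(D$inc))
  if (!length(cl)) return(rep(FALSE, length(D$diagnoses)))
  rowSums(D$inc[, cl, drop = FALSE]) > 0
}

#' Update a diagnosis set on a probe answer
#'
#' A passed test leaves the set unchanged (under the weak fault model a
#' pass never exonerates).  A failed test of `comp` keeps exactly the
#' diagnoses containing `comp` or one of its ancestors, then renormalizes
#' the surviving probabilities.
#'
#' @param D a `diagnosis_set`
#' @param comp the probed component id
#' @param test_ok logical probe answer (`TRUE` = passed)
#' @return the updated `diagnosis_set`
#' @section Errors: if a failed answer eliminates every candidate the
#'   answer is inconsistent with the minimal-diagnosis assumption and an
#'   error of class `physdx_inconsistent_answer` is raised.
#' @export
update_on_answer <- function(D, comp, test_ok) {
  stopifnot(inherits(D, "diagnosis_set"), is.logical(test_ok), !is.na(test_ok))
  am_check_id(D$model, comp)
  if (test_ok) return(D)
  keep <- fail_survivors(D, comp)
  if (!any(keep)) {
    physdx_error("physdx_inconsistent_answer",
                 paste0("failed test of '", comp,
                        "' is inconsistent with every candidate diagnosis"))
  }
  D$diagnoses <- D$diagnoses[keep]
  D$prob <- D$prob[keep] / sum(D$prob[keep])
  D$inc <- D$inc[keep, , drop = FALSE]
  D
}

#' Expected information gain of a probe
#'
#' The entropy reduction a probe of `comp` is expected to achieve.  Under
#' the weak fault model a pass leaves the set unchanged, so only the fail
#' branch is informative:
#' `IG = P_fail * (Ent(D) - Ent(D | comp failed))`, with
#' `P_fail = sum of P(delta) over diagnoses intersecting the closure of comp`.
#' `mode = "optimistic"` instead reports the raw fail-branch reduction
#' `Ent(D) - Ent(D | comp failed)` without weighting by `P_fail`.
#'
#' @inheritParams update_on_answer
#' @param mode `"expected"` (default) or `"optimistic"`
#' @return gain in bits, always >= 0
#' @export
expected_information_gain <- function(D, comp, mode = c("expected", "optimistic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(D, "diagnosis_set"))
  am_check_id(D$model, comp)
  keep <- fail_survivors(D, comp)
  p_fail <- sum(D$prob[keep])
  if (p_fail <= 0 || all(keep)) return(0)
  q <- D$prob[keep] / p_fail
  q <- q[q > 0]
  gain <- diagnosis_entropy(D) + sum(q * log2(q))
  gain <- max(0, gain)
  if (mode == "expected") p_fail * gain else gain
}

#' Run the sequential probing loop
#'
#' Iteratively selects a component to test, queries the answer oracle,
#' and filters the diagnosis set, until the set can no longer shrink:
#' the loop stops when at most one candidate remains, when no untested
#' probe candidates remain, or (information-gain policy) when every
#' remaining candidate has zero expected gain.  The information-gain
#' policy probes the candidate with maximal [expected_information_gain()],
#' breaking ties uniformly at random; the random baseline draws the probe
#' uniformly from the candidates.
#'
#' @param D a `diagnosis_set` to start from
#' @param oracle a function `component id -> logical` answering whether the
#'   test passed; must be deterministic within a session (see
#'   [oracle_from_scenario()])
#' @param policy `"info_gain"` or `"random"`
#' @param seed integer seed driving tie-breaks / random probe choice
#' @param max_probes optional cap on the number of probes
#' @param ig_mode gain semantics passed to [expected_information_gain()]
#' @return an object of class `probe_session`: list with `final` (the
#'   final `diagnosis_set`) and `log` (data frame with columns `probe`,
#'   `expected_gain`, `answer`, `set_size_after`)
#' @section Errors: an inconsistent answer aborts the session with an
#'   error of class `physdx_inconsistent_answer` carrying the partial
#'   `log` as a condition field.
#' @export
run_probing <- function(D, oracle, policy = c("info_gain", "random"),
                        seed = 1L, max_probes = Inf,
                        ig_mode = c("expected", "optimistic")) {
  policy <- match.arg(policy)
  ig_mode <- match.arg(ig_mode)
  stopifnot(inherits(D, "diagnosis_set"), is.function(oracle))
  log <- data.frame(probe = character(), expected_gain = numeric(),
                    answer = logical(), set_size_after = integer(),
                    stringsAsFactors = FALSE)
  with_seed(seed, {
    tested <- character()
    repeat {
      if (length(D$diagnoses) <= 1 || nrow(log) >= max_probes) break
      cands <- candidate_probes(D, tested)
      if (!length(cands)) break
      gains <- vapply(cands, expected_information_gain, numeric(1),
                      D = D, mode = ig_mode)
      if (policy == "info_gain") {
        if (max(gains) <= 1e-12) break
        best <- cands[gains >= max(gains) - 1e-12]
        probe <- if (length(best) > 1) sample(best, 1) else best
      } else {
        probe <- if (length(cands) > 1) sample(cands, 1) else cands
      }
      answer <- isTRUE(oracle(probe))
      D <- tryCatch(
        update_on_answer(D, probe, answer),
        physdx_inconsistent_answer = function(e) {
          e$log <- log
          e$probe <- probe
          stop(e)
        })
      tested <- c(tested, probe)
      log[nrow(log) + 1, ] <- list(probe, gains[[match(probe, cands)]],
                                   answer, length(D$diagnoses))
    }
  })
  structure(list(final = D, log = log, policy = policy, seed = seed),
            class = "probe_session")
}

#' @export
print.probe_session <- function(x, ...) {
  cat("Probing session (", x$policy, " policy, seed ", x$seed, "): ",
      nrow(x$log), " probes\n", sep = "")
  if (nrow(x$log)) {
    cat(sprintf("  %-24s gain %5.3f  %s  -> %d candidates\n",
                x$log$probe, x$log$expected_gain,
                ifelse(x$log$answer, "pass", "FAIL"),
                x$log$set_size_after), sep = "")
  }
  print(x$final)
  invisible(x)
}

#' @export
plot.probe_session <- function(x, ..., start_size = NULL) {
  sizes <- c(if (!is.null(start_size)) start_size, x$log$set_size_after)
  graphics::plot(seq_along(sizes) - as.integer(!is.null(start_size)), sizes,
                 type = "s", xlab = "probe", ylab = "|diagnosis set|", ...)
  invisible(x)
}

#' Write a session log as JSON lines
#' @param session a `probe_session`
#' @param path output path (one probe record per line)
#' @return `path`, invisibly
#' @export
write_session_log <- function(session, path) {
  stopifnot(inherits(session, "probe_session"))
  lines <- vapply(seq_len(nrow(session$log)), function(i) {
    jsonlite::toJSON(as.list(session$log[i, ]), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
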