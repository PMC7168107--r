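diag_key <- function(delta) paste(sort(delta), collapse = "\r")

#' Probability-weighted false positive rate of a diagnosis set
#'
#' For each diagnosis `delta`, `FPR = FP / (FP + TN)` with
#' `FP = |delta \ faults|` (suspected but healthy) and
#' `TN = |faultable \ (delta U faults)|` (cleared and healthy); both
#' counted over faultable components only, since dermatomes can never be
#' true or predicted positives.  The set-level value is the
#' probability-weighted mean over the diagnoses.  A diagnosis with
#' `FP + TN = 0` contributes 0 and the result carries attribute
#' `zero_denominator = TRUE`.
#'
#' @param D a `diagnosis_set`
#' @param faults character vector: the true fault set
#' @return weighted FPR in `[0, 1]`
#' @export
weighted_fpr <- function(D, faults) {
  stopifnot(inherits(D, "diagnosis_set"))
  fcomp <- D$model$faultable
  faults <- intersect(faults, fcomp)
  sz <- lengths(D$diagnoses)
  overlap <- if (length(faults)) {
    rowSums(D$inc[, faults, drop = FALSE])
  } else {
    numeric(length(sz))
  }
  fp <- sz - overlap
  tn <- length(fcomp) - (sz + length(faults) - overlap)
  denom <- fp + tn
  term <- ifelse(denom > 0, fp / denom, 0)
  out <- sum(D$prob * term)
  if (any(denom == 0)) attr(out, "zero_denominator") <- TRUE
  out
}

#' ROC AUC of a health state against the true faults
#'
#' Thresholds the health state at 0, 0.1, ..., 1; at each threshold the
#' components with health state *strictly greater* than the threshold are
#' predicted faulty, yielding an (FPR, TPR) point over the faultable
#' components.  The corner points (0,0) and (1,1) are added and the ROC
#' curve is integrated by the trapezoid rule after sorting by FPR (TPR as
#' tie-break).
#'
#' @param model an [anatomy_model()]
#' @param H named health-state vector (see [health_state()])
#' @param faults character vector: the true fault set (non-empty)
#' @return AUC in `[0, 1]`
#' @export
health_auc <- function(model, H, faults) {
  fcomp <- model$faultable
  faults <- intersect(faults, fcomp)
  if (!length(faults)) {
    physdx_error("physdx_undefined_metric",
                 "AUC is undefined without faulty components")
  }
  h <- H[fcomp]
  pos <- fcomp %in% faults
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  pts <- t(vapply(seq(0, 1, by = 0.1), function(t) {
    pred <- h > t
    c(fpr = if (n_neg) sum(pred & !pos) / n_neg else 0,
      tpr = sum(pred & pos) / n_pos)
  }, numeric(2)))
  pts <- rbind(pts, c(0, 0), c(1, 1))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  sum(diff(pts[, 1]) * (head(pts[, 2], -1) + pts[-1, 2]) / 2)
}

#' Is the true fault set among the top-K diagnoses?
#'
#' Diagnoses are ranked by decreasing probability, ties broken by
#' cardinality then lexicographic component order for determinism; the
#' check requires exact set equality with one of the first `K`.
#'
#' @param D a `diagnosis_set`
#' @param faults character vector: the true fault set
#' @param K how many top diagnoses to inspect
#' @return `TRUE` or `FALSE`
#' @export
top_k_contains <- function(D, faults, K) {
  stopifnot(inherits(D, "diagnosis_set"), K >= 1)
  keys <- vapply(D$diagnoses, diag_key, character(1))
  # constructor already orders by (-prob, size, lexicographic)
  diag_key(faults) %in% head(keys, K)
}

#' Expected wasted inspection effort of a health state
#'
#' Suppose components are physically inspected in strictly decreasing
#' health-state order until every true fault has been inspected.  The
#' wasted effort is the expected number of *healthy* faultable components
#' inspected along the way: all healthy components ranked strictly above
#' the lowest-ranked fault, plus — within the tie group at that fault's
#' health value — the expected number of tied healthy components drawn
#' before the last tied fault under a uniformly random tie order
#' (`m * r / (r + 1)` for `m` tied healthy and `r` tied faulty).
#'
#' @inheritParams health_auc
#' @return non-negative expected count
#' @export
wasted_effort <- function(model, H, faults) {
  fcomp <- model$faultable
  faults <- intersect(faults, fcomp)
  stopifnot(length(faults) >= 1)
  h <- H[fcomp]
  healthy <- !(fcomp %in% faults)
  hstar <- min(h[!healthy])
  tol <- 1e-12
  above <- h > hstar + tol
  tie <- abs(h - hstar) <= tol
  m <- sum(tie & healthy)
  r <- sum(tie & !healthy)
  sum(above & healthy) + m * r / (r + 1)
}

metric_row <- function(D, faults) {
  H <- health_state(D)
  c(list(set_size = length(D$diagnoses),
         wfpr = as.numeric(weighted_fpr(D, faults)),
         auc = health_auc(D$model, H, faults),
         wasted = wasted_effort(D$model, H, faults)),
    setNames(lapply(1:5, function(K) top_k_contains(D, faults, K)),
             paste0("top", 1:5)))
}

#' Evaluate a scenario batch before and after troubleshooting
#'
#' For every scenario: diagnose the initial observations, record the
#' "before" metrics, run the probing loop against the scenario's answer
#' oracle, and record the "after" metrics from the final (renormalized)
#' diagnosis set.  Aggregates per-cardinality means and an improvement
#' table.  Improvements are oriented so that a positive entry always
#' means troubleshooting helped: before minus after for set size,
#' weighted FPR and wasted effort; after minus before for AUC and the
#' top-K hit rates.
#'
#' Scenarios whose probing session aborts on an inconsistent answer are
#' excluded from aggregation and counted in `n_excluded`.
#'
#' @param model an [anatomy_model()]
#' @param scenarios a `sim_batch` or list of `gt_scenario`
#' @param policy probing policy, `"info_gain"` or `"random"`
#' @param prior prior fault probability passed to [diagnose()]
#' @param seed integer seed driving the per-scenario probing seeds
#' @param max_probes optional cap on probes per session
#' @return an object of class `metrics_report`: list with `records` (one
#'   row per scenario), `per_cardinality` (means of every metric),
#'   `improvement` (metric x cardinality), `probe_curves` (mean
#'   diagnosis-set size after each probe, per cardinality), `n_excluded`
#' @export
evaluate_batch <- function(model, scenarios, policy = c("info_gain", "random"),
                           prior = 0.1, seed = 1L, max_probes = Inf) {
  policy <- match.arg(policy)
  if (inherits(scenarios, "sim_batch")) scenarios <- scenarios$scenarios
  stopifnot(length(scenarios) >= 1)
  rows <- vector("list", length(scenarios))
  curves <- vector("list", length(scenarios))
  n_excluded <- 0L
  session_seeds <- with_seed(seed,
                             sample.int(.Machine$integer.max, length(scenarios)))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    D0 <- diagnose(model, sc$initial_obs, prior)
    before <- metric_row(D0, sc$faults)
    session <- tryCatch(
      run_probing(D0, oracle_from_scenario(sc), policy,
                  seed = session_seeds[i], max_probes = max_probes),
      physdx_inconsistent_answer = function(e) NULL)
    if (is.null(session)) {
      n_excluded <- n_excluded + 1L
      next
    }
    after <- metric_row(session$final, sc$faults)
    rows[[i]] <- data.frame(
      scenario = i, k = sc$k,
      seed = if (is.null(sc$seed)) NA_integer_ else sc$seed,
      probes_used = nrow(session$log),
      retained = top_k_contains(session$final, sc$faults,
                                length(session$final$diagnoses)),
      as.data.frame(setNames(before, paste0(names(before), "_before"))),
      as.data.frame(setNames(after, paste0(names(after), "_after"))))
    curves[[i]] <- list(k = sc$k,
                        curve = c(before$set_size, session$log$set_size_after))
  }
  keep <- !vapply(rows, is.null, logical(1))
  records <- do.call(rbind, rows[keep])
  curves <- curves[keep]

  agg <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) | vapply(df, is.logical, logical(1))
    out <- aggregate(df[num & names(df) != "k"], by = list(k = df$k), FUN = mean)
    out[order(out$k), ]
  }
  per_k <- agg(records)

  imp <- data.frame(k = per_k$k)
  imp$set_size <- per_k$set_size_before - per_k$set_size_after
  imp$wfpr <- per_k$wfpr_before - per_k$wfpr_after
  imp$auc <- per_k$auc_after - per_k$auc_before
  imp$wasted <- per_k$wasted_before - per_k$wasted_after
  for (K in 1:5) {
    imp[[paste0("top", K)]] <-
      per_k[[paste0("top", K, "_after")]] - per_k[[paste0("top", K, "_before")]]
  }
  rel <- imp
  rel$set_size <- imp$set_size / per_k$set_size_before
  rel$wfpr <- ifelse(per_k$wfpr_before > 0, imp$wfpr / per_k$wfpr_before, NA)
  rel$auc <- ifelse(per_k$auc_before > 0, imp$auc / per_k$auc_before, NA)
  rel$wasted <- ifelse(per_k$wasted_before > 0, imp$wasted / per_k$wasted_before, NA)

  mean_curves <- lapply(split(curves, vapply(curves, `[[`, numeric(1), "k")),
                        function(cs) {
                          len <- max(vapply(cs, function(c) length(c$curve), integer(1)))
                          padded <- vapply(cs, function(c) {
                            cv <- c$curve
                            c(cv, rep(cv[length(cv)], len - length(cv)))
                          }, numeric(len))
                          rowMeans(matrix(padded, nrow = len))
                        })

  structure(list(records = records, per_cardinality = per_k,
                 improvement = imp, improvement_relative = rel,
                 probe_curves = mean_curves, n_excluded = n_excluded,
                 policy = policy, prior = prior, seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Troubleshooting evaluation (", x$policy, " policy, ",
      nrow(x$records), " scenarios",
      if (x$n_excluded) paste0(", ", x$n_excluded, " excluded"), ")\n", sep = "")
  cat("Mean improvement (positive = troubleshooting helped) per cardinality:\n")
  print(format(x$improvement, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.metrics_report <- function(x, which = c("set_size", "wfpr", "auc", "curves"),
                                ...) {
  which <- match.arg(which)
  pk <- x$per_cardinality
  if (which == "curves") {
    len <- max(vapply(x$probe_curves, length, integer(1)))
    graphics::plot(NULL, xlim = c(0, len - 1),
                   ylim = c(0, max(vapply(x$probe_curves, max, numeric(1)))),
                   xlab = "probes", ylab = "mean |diagnosis set|", ...)
    for (i in seq_along(x$probe_curves)) {
      cv <- x$probe_curves[[i]]
      graphics::lines(seq_along(cv) - 1, cv, col = i)
    }
    graphics::legend("topright", legend = paste0("k=", names(x$probe_curves)),
                     col = seq_along(x$probe_curves), lty = 1, cex = 0.8)
    return(invisible(x))
  }
  cols <- paste0(which, c("_before", "_after"))
  m <- t(as.matrix(pk[, cols]))
  graphics::barplot(m, beside = TRUE, names.arg = pk$k,
                    xlab = "number of injected faults", ylab = which,
                    col = c("steelblue", "seagreen"),
                    legend.text = c("before", "after"), ...)
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#' @param report a `metrics_report`
#' @param csv_path per-scenario records CSV; `NULL` to skip
#' @param json_path summary JSON (per-cardinality means + improvement
#'   tables); `NULL` to skip
#' @return `report`, invisibly
#' @export
write_metrics <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  if (!is.null(csv_path)) {
    write.csv(report$records, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_cardinality = report$per_cardinality,
           improvement = report$improvement,
           improvement_relative = report$improvement_relative,
           probe_curves = report$probe_curves,
           n_excluded = report$n_excluded,
           policy = report$policy, prior = report$prior, seed = report$seed),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
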