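#' Per-sample precision/recall against the reference standard
#'
#' For every sample, precision and recall are computed separately for the
#' non-expressed class (reference inactive genes as positives) and the
#' expressed class (reference active genes as positives), restricted to the
#' unambiguous reference genes present in the calls. Samples where a class
#' has zero predicted positives have undefined precision for that class; such
#' values are recorded as missing and excluded from the mean/SD, with a
#' logged count.
#'
#' @param calls A single `state_call_set` or a list of them (one per sample).
#' @param ref Reference standard (see [build_reference_standard()]), or any
#'   data frame with columns `gene_id` and `label` in
#'   `{active, inactive, ambiguous}`.
#' @param method_name Label stored in the report.
#' @return An `evaluation_report`: list with `method_name`, `summary` (mean
#'   and sample SD per class x metric), and `per_sample` raw values.
#' @export
evaluate_per_sample <- function(calls, ref, method_name = NULL) {
  if (inherits(calls, "state_call_set")) calls <- list(calls)
  ts_assert(length(calls) >= 1 && all(vapply(calls, inherits, logical(1),
                                             "state_call_set")),
            "calls must be one or more state_call_set objects",
            "ts_shape_error")
  ts_assert(all(c("gene_id", "label") %in% names(ref)),
            "reference standard needs gene_id and label columns",
            "ts_evaluation_error")
  ref <- ref[ref$label != "ambiguous", , drop = FALSE]
  ts_assert(any(ref$label == "active") && any(ref$label == "inactive"),
            "reference standard must contain both active and inactive genes",
            "ts_evaluation_error")
  if (is.null(method_name)) method_name <- attr(calls[[1]], "method")
  per_sample <- do.call(rbind, lapply(calls, function(cs) {
    idx <- match(ref$gene_id, cs$gene_id)
    ok <- !is.na(idx)
    lab <- ref$label[ok]
    state <- cs$state[idx[ok]]
    rows <- lapply(c("non_expressed", "expressed"), function(cls) {
      if (cls == "non_expressed") {
        pred <- state == 0L; pos <- lab == "inactive"
      } else {
        pred <- state == 1L; pos <- lab == "active"
      }
      tp <- sum(pred & pos)
      precision <- if (sum(pred) == 0) NA_real_ else tp / sum(pred)
      recall <- tp / sum(pos)
      data.frame(sample_id = attr(cs, "sample_id"), class = cls,
                 precision = precision, recall = recall,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  n_undef <- sum(is.na(per_sample$precision))
  if (n_undef > 0) {
    ts_log("warn", sprintf(
      "%d sample/class combination(s) with undefined precision excluded",
      n_undef))
  }
  summary <- do.call(rbind, lapply(c("non_expressed", "expressed"),
                                   function(cls) {
    sub <- per_sample[per_sample$class == cls, , drop = FALSE]
    do.call(rbind, lapply(c("precision", "recall"), function(metric) {
      v <- sub[[metric]]
      used <- v[!is.na(v)]
      data.frame(class = cls, metric = metric,
                 mean = mean(used),
                 sd = if (length(used) > 1) sd(used) else 0,
                 n_samples = length(used),
                 n_undefined = sum(is.na(v)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL
  structure(list(method_name = method_name, summary = summary,
                 per_sample = per_sample),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: method %s over %d sample(s)\n",
              x$method_name, length(unique(x$per_sample$sample_id))))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Tissue-level precision-recall curve over the non-expressed ratio
#'
#' Sweeps the non-expressed-ratio threshold over all distinct observed
#' values (in decreasing order, so recall is non-decreasing along the sweep);
#' at each threshold, genes with ratio at or above it are predicted
#' non-expressed and scored against the reference inactive class as the
#' positive class. The area under the curve is the trapezoidal integral of
#' precision over recall, anchored at recall 0 with the precision of the
#' top-ranked prediction set. Precision at the fixed dormancy threshold
#' (0.9 by default) is also reported.
#'
#' @param ratios Rows of [tissue_ratios()] for a single tissue.
#' @param ref Reference standard (see [evaluate_per_sample()]).
#' @param fixed_threshold Operating point at which to report precision.
#' @param min_overlap Minimum number of unambiguous reference genes shared
#'   with `ratios`.
#' @return A `pr_curve`: list with `points` (threshold, n_predicted,
#'   precision, recall), `auprc`, `precision_at_fixed`, `fixed_threshold`,
#'   and `n_genes`.
#' @export
tissue_pr_curve <- function(ratios, ref, fixed_threshold = 0.9,
                            min_overlap = 10L) {
  ts_assert(all(c("gene_id", "non_expressed_ratio") %in% names(ratios)),
            "ratios must come from tissue_ratios()", "ts_shape_error")
  if ("tissue" %in% names(ratios)) {
    ts_assert(length(unique(ratios$tissue)) == 1,
              "ratios must cover exactly one tissue", "ts_evaluation_error")
  }
  ref <- ref[ref$label != "ambiguous", , drop = FALSE]
  idx <- match(ref$gene_id, ratios$gene_id)
  ok <- !is.na(idx)
  ts_assert(sum(ok) >= min_overlap,
            sprintf("only %d unambiguous genes shared with the ratios (need >= %d)",
                    sum(ok), min_overlap),
            "ts_evaluation_error")
  score <- ratios$non_expressed_ratio[idx[ok]]
  positive <- ref$label[ok] == "inactive"
  n_pos <- sum(positive)
  ts_assert(n_pos > 0 && n_pos < length(positive),
            "reference overlap must contain both classes",
            "ts_evaluation_error")
  thresholds <- sort(unique(score), decreasing = TRUE)
  points <- do.call(rbind, lapply(thresholds, function(t) {
    pred <- score >= t
    tp <- sum(pred & positive)
    data.frame(threshold = t, n_predicted = sum(pred),
               precision = tp / sum(pred), recall = tp / n_pos)
  }))
  r <- c(0, points$recall)
  p <- c(points$precision[1], points$precision)
  auprc <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  pred_fixed <- score >= fixed_threshold
  precision_at_fixed <- if (any(pred_fixed)) {
    sum(pred_fixed & positive) / sum(pred_fixed)
  } else NA_real_
  structure(list(points = points, auprc = auprc,
                 precision_at_fixed = precision_at_fixed,
                 fixed_threshold = fixed_threshold,
                 n_genes = length(score)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("pr_curve over %d genes: AUPRC = %.4f; precision at ratio >= %.2f: %s\n",
              x$n_genes, x$auprc, x$fixed_threshold,
              ifelse(is.na(x$precision_at_fixed), "undefined",
                     sprintf("%.4f", x$precision_at_fixed))))
  invisible(x)
}
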