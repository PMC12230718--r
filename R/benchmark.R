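# Predictor evaluation on labelled control sets. Truth is per record: one
# true positive is one positive-control sequence carrying at least one
# qualifying prediction. Balanced accuracy accompanies the usual metrics
# because control sets for this problem are heavily imbalanced (few
# validated positives, many negatives).

#' Evaluate predictions against labelled controls
#'
#' A record counts as called positive when it has at least one prediction in
#' the requested confidence tier (`"overall"` accepts any tier). Metrics are
#' percentages: sensitivity `100*tp/(tp+fn)`, specificity `100*tn/(tn+fp)`,
#' precision `100*tp/(tp+fp)` and balanced accuracy, the mean of sensitivity
#' and specificity. A metric whose denominator is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param predictions data.frame with columns `seq_id` and `pooled_tier`
#'   (`"high"`, `"medium"`, `"low"`); zero rows for a record means no call.
#' @param labels data.frame with columns `seq_id` and `label`
#'   (`"pos"`/`"neg"`), one row per control record.
#' @param tier `"overall"`, `"high"`, `"medium"` or `"low"`.
#' @return A list of class `ire_benchmark`: `tier`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `precision`, `balanced_accuracy`
#'   (percentages, 2 decimals).
#' @examples
#' labels <- data.frame(seq_id = c("a", "b", "c"),
#'                      label = c("pos", "pos", "neg"))
#' preds <- data.frame(seq_id = "a", pooled_tier = "high")
#' evaluate_predictions(preds, labels)$sensitivity  # 50
#' @export
evaluate_predictions <- function(predictions, labels,
                                 tier = c("overall", "high", "medium", "low")) {
  tier <- match.arg(tier)
  stopifnot(all(c("seq_id", "pooled_tier") %in% names(predictions)),
            all(c("seq_id", "label") %in% names(labels)))
  if (!all(labels$label %in% c("pos", "neg"))) {
    stop("labels must be 'pos' or 'neg'")
  }
  if (anyDuplicated(labels$seq_id)) {
    stop("duplicate seq_id in labels: ",
         paste(unique(labels$seq_id[duplicated(labels$seq_id)]),
               collapse = ", "))
  }
  orphans <- setdiff(predictions$seq_id, labels$seq_id)
  if (length(orphans)) {
    stop("predictions name record(s) absent from the labels: ",
         paste(sort(unique(orphans)), collapse = ", "))
  }
  kept <- if (tier == "overall") predictions else
    predictions[predictions$pooled_tier == tier, , drop = FALSE]
  called <- labels$seq_id %in% kept$seq_id
  pos <- labels$label == "pos"
  tp <- sum(called & pos); fn <- sum(!called & pos)
  fp <- sum(called & !pos); tn <- sum(!called & !pos)
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 2)
  sens <- pct(tp, tp + fn)
  spec <- pct(tn, tn + fp)
  structure(list(tier = tier, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 precision = pct(tp, tp + fp),
                 balanced_accuracy = if (is.na(sens) || is.na(spec))
                   NA_real_ else round((sens + spec) / 2, 2)),
            class = "ire_benchmark")
}

#' Benchmark report across tiers
#'
#' Runs [evaluate_predictions()] overall and for each pooled confidence
#' tier, mirroring how performance is reported per confidence level.
#'
#' @inheritParams evaluate_predictions
#' @param tiers Tiers to evaluate.
#' @return data.frame with one row per tier and the four metrics plus
#'   confusion counts.
#' @export
benchmark_report <- function(predictions, labels,
                             tiers = c("overall", "high", "medium", "low")) {
  rows <- lapply(tiers, function(t) {
    r <- evaluate_predictions(predictions, labels, t)
    data.frame(tier = r$tier, tp = r$tp, fp = r$fp, tn = r$tn, fn = r$fn,
               sensitivity = r$sensitivity, specificity = r$specificity,
               precision = r$precision,
               balanced_accuracy = r$balanced_accuracy)
  })
  do.call(rbind, rows)
}

#' @export
print.ire_benchmark <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("Benchmark (%s tier): tp %d, fp %d, tn %d, fn %d\n",
              x$tier, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %s, specificity %s, precision %s, balanced accuracy %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$precision),
              fmt(x$balanced_accuracy)))
  invisible(x)
}
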