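#' Classify observed log-fold-changes into up / down / unaltered
#'
#' A gene whose absolute log-fold-change is lower than the threshold is
#' considered non-altered; at or beyond the threshold the sign decides the
#' direction (the boundary value itself counts as altered).
#'
#' @param logfc Numeric vector of observed log2 fold changes (finite).
#' @param threshold Positive magnitude threshold (default 0.6).
#' @return Character vector in `{"up", "down", "unaltered"}`.
#' @examples
#' classify_logfc(c(0.7, -0.7, 0.3, 0.6))
#' @export
classify_logfc <- function(logfc, threshold = 0.6) {
  stopifnot(threshold > 0)
  if (any(!is.finite(logfc))) {
    abort("logfc values must be finite")
  }
  dplyr::case_when(
    logfc >= threshold ~ "up",
    logfc <= -threshold ~ "down",
    TRUE ~ "unaltered"
  )
}

#' Map simulated activity scores to predicted states
#'
#' The score's sign is the predicted direction of effect: positive scores
#' predict up-regulation, negative scores down-regulation, and a zero score
#' predicts no alteration.
#'
#' @param activity_score Numeric vector of activity scores.
#' @return Character vector in `{"up", "down", "unaltered"}`.
#' @export
classify_prediction <- function(activity_score) {
  dplyr::case_when(
    activity_score > 0 ~ "up",
    activity_score < 0 ~ "down",
    TRUE ~ "unaltered"
  )
}

#' Benchmark predictions against observed alteration states
#'
#' Builds the two class-specific confusion tables used to benchmark the
#' simulator and derives their rates.
#'
#' For genes observed as altered, predictions are scored by sign
#' agreement: `TP` = predicted up & observed up, `TN` = predicted down &
#' observed down, `FP` = predicted up & observed down, `FN` = predicted down
#' & observed up. `PPV = TP/(TP+FP)`, `Sensitivity = TP/(TP+FN)`,
#' `Specificity = TN/(TN+FP)`.
#'
#' For genes observed as non-altered, a prediction of "unaltered" is a true
#' positive and a prediction of altered a false negative, giving
#' `FNR = FN/(FN+TP)`; genes predicted unaltered but observed altered are the
#' false positives of this class, entering `ppv_unaltered = TP/(TP+FP)`.
#'
#' Overall accuracy is the fraction of genes whose predicted state equals the
#' observed one. Rates with a zero denominator are reported as `NA`.
#'
#' @param data A data frame with columns `node_id`, `predicted`, `observed`,
#'   each state in `{"up", "down", "unaltered"}`. Alternatively pass two
#'   named character vectors via `predicted` and `observed` with
#'   `data = NULL`.
#' @param predicted,observed Optional named vectors used when `data` is
#'   `NULL`; names are node ids and must match between the two.
#' @return An object of class `evaluation_report`; see
#'   [glance.evaluation_report()].
#' @export
evaluate_predictions <- function(data = NULL, predicted = NULL, observed = NULL) {
  if (is.null(data)) {
    if (is.null(predicted) || is.null(observed)) {
      abort("supply either data or both predicted and observed")
    }
    miss <- union(
      setdiff(names(observed), names(predicted)),
      setdiff(names(predicted), names(observed))
    )
    if (length(miss) > 0) {
      abort(sprintf(
        "node id(s) present in only one of predicted/observed: %s",
        paste(head(miss, 10), collapse = ", ")
      ))
    }
    data <- tibble(
      node_id = names(observed),
      predicted = unname(predicted[names(observed)]),
      observed = unname(observed)
    )
  }
  data <- as_tibble(data)
  if (!all(c("node_id", "predicted", "observed") %in% names(data))) {
    abort("data needs columns node_id, predicted, observed")
  }
  if (nrow(data) == 0) {
    abort("no shared nodes to evaluate")
  }
  states <- c("up", "down", "unaltered")
  bad <- setdiff(unique(c(data$predicted, data$observed)), states)
  if (length(bad) > 0) {
    abort(sprintf("unknown state(s): %s", paste(bad, collapse = ", ")))
  }

  pred <- data$predicted
  obs <- data$observed
  tp <- sum(pred == "up" & obs == "up")
  tn <- sum(pred == "down" & obs == "down")
  fp <- sum(pred == "up" & obs == "down")
  fn <- sum(pred == "down" & obs == "up")
  # unaltered class: misses of truly altered genes are its false positives
  tp_u <- sum(pred == "unaltered" & obs == "unaltered")
  fn_u <- sum(pred != "unaltered" & obs == "unaltered")
  fp_u <- sum(pred == "unaltered" & obs != "unaltered")

  rate <- function(num, den) if (den > 0) num / den else NA_real_

  structure(
    list(
      n = nrow(data),
      altered = c(TP = tp, TN = tn, FP = fp, FN = fn),
      unaltered = c(TP = tp_u, FN = fn_u, FP = fp_u),
      accuracy = mean(pred == obs),
      ppv = rate(tp, tp + fp),
      sensitivity = rate(tp, tp + fn),
      specificity = rate(tn, tn + fp),
      ppv_unaltered = rate(tp_u, tp_u + fp_u),
      fnr_unaltered = rate(fn_u, fn_u + tp_u)
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  genes scored: %d, accuracy %.4f\n", x$n, x$accuracy))
  cat(sprintf(
    "  altered class: TP=%d TN=%d FP=%d FN=%d | PPV=%s Sens=%s Spec=%s\n",
    x$altered["TP"], x$altered["TN"], x$altered["FP"], x$altered["FN"],
    format(x$ppv, digits = 4), format(x$sensitivity, digits = 4),
    format(x$specificity, digits = 4)
  ))
  cat(sprintf(
    "  unaltered class: TP=%d FN=%d FP=%d | PPV=%s FNR=%s\n",
    x$unaltered["TP"], x$unaltered["FN"], x$unaltered["FP"],
    format(x$ppv_unaltered, digits = 4), format(x$fnr_unaltered, digits = 4)
  ))
  invisible(x)
}

#' Tidy / summarise an evaluation report
#'
#' @param x An `evaluation_report` from [evaluate_predictions()].
#' @param ... Unused.
#' @return `tidy()` gives a long metric/value tibble; `glance()` one wide
#'   row.
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble(
    metric = c(
      "accuracy", "ppv", "sensitivity", "specificity",
      "ppv_unaltered", "fnr_unaltered"
    ),
    value = c(
      x$accuracy, x$ppv, x$sensitivity, x$specificity,
      x$ppv_unaltered, x$fnr_unaltered
    )
  )
}

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(
    n = x$n, accuracy = x$accuracy,
    TP = x$altered[["TP"]], TN = x$altered[["TN"]],
    FP = x$altered[["FP"]], FN = x$altered[["FN"]],
    TP_unaltered = x$unaltered[["TP"]], FN_unaltered = x$unaltered[["FN"]],
    FP_unaltered = x$unaltered[["FP"]],
    ppv = x$ppv, sensitivity = x$sensitivity, specificity = x$specificity,
    ppv_unaltered = x$ppv_unaltered, fnr_unaltered = x$fnr_unaltered
  )
}

#' Flag non-expressed genes from an expression table
#'
#' Sequencing data: genes with an average count below 10 are considered not
#' expressed. Microarray data: genes whose average expression falls below the
#' 10th percentile of all gene averages (linear-interpolation percentile).
#'
#' @param expression A data frame with a `node_id` column and one numeric
#'   column per sample.
#' @param platform `"sequencing"` or `"microarray"`.
#' @param count_threshold Mean-count cutoff for sequencing (default 10).
#' @param percentile Quantile cutoff for microarray (default 0.1).
#' @return Character vector of flagged node ids.
#' @export
detect_nonexpressed <- function(expression, platform = c("sequencing", "microarray"),
                                count_threshold = 10, percentile = 0.1) {
  platform <- match.arg(platform)
  expression <- as_tibble(expression)
  if (!"node_id" %in% names(expression) || ncol(expression) < 2) {
    abort("expression needs a node_id column and at least one sample column")
  }
  vals <- as.matrix(expression[setdiff(names(expression), "node_id")])
  if (!is.numeric(vals) || nrow(vals) == 0) {
    abort("expression sample columns must be numeric and non-empty")
  }
  means <- rowMeans(vals)
  flagged <- if (platform == "sequencing") {
    means < count_threshold
  } else {
    means < quantile(means, percentile, type = 7)
  }
  expression$node_id[flagged]
}
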