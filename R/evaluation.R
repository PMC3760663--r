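#' Per-category confusion counts under inconclusive-as-negative
#'
#' Forensic eye-colour calling is evaluated one category at a time. A sample
#' is positive-called for a category iff its call equals that category;
#' inconclusive calls and calls to any other category are negative calls.
#' False negatives therefore include inconclusives of true positives (they
#' lower sensitivity) and inconclusives of true negatives count as true
#' negatives (they raise specificity) — the conservative convention used in
#' forensic DNA phenotyping.
#'
#' @param calls Tibble with `sample_id` and `call` (values in
#'   `c(eye_colours(), "inconclusive")`), e.g. a [predict_eye_colour()]
#'   result.
#' @param truth Tibble with `sample_id` and `eye_colour`.
#' @param categories Categories to tabulate (default all three).
#' @return A tibble with columns `category`, `tp`, `fp`, `tn`, `fn`;
#'   counts per category sum to the cohort size.
#' @export
confusion_counts <- function(calls, truth, categories = eye_colours()) {
  dat <- align_by_sample(calls, truth)
  purrr::map_dfr(categories, function(cat) {
    pos_call <- dat$call == cat
    pos_true <- dat$eye_colour == cat
    tibble(
      category = cat,
      tp = sum(pos_call & pos_true),
      fp = sum(pos_call & !pos_true),
      tn = sum(!pos_call & !pos_true),
      fn = sum(!pos_call & pos_true)
    )
  })
}

# strict 1:1 alignment of two per-sample tables; lists offenders on mismatch
align_by_sample <- function(calls, truth) {
  only_calls <- setdiff(calls$sample_id, truth$sample_id)
  only_truth <- setdiff(truth$sample_id, calls$sample_id)
  if (length(only_calls) > 0 || length(only_truth) > 0 ||
      anyDuplicated(calls$sample_id) || anyDuplicated(truth$sample_id)) {
    abort(paste0(
      "calls and truth must share identical unique sample_ids; ",
      "only in calls: {", paste(head(only_calls, 5), collapse = ", "), "}, ",
      "only in truth: {", paste(head(only_truth, 5), collapse = ", "), "}"
    ), class = "irisplexr_align_error")
  }
  dplyr::inner_join(calls, truth, by = "sample_id")
}

#' Accuracy metrics from confusion counts
#'
#' Sensitivity = 100·tp/(tp+fn), specificity = 100·tn/(tn+fp),
#' PPV = 100·tp/(tp+fp), NPV = 100·tn/(tn+fn), all as percentages.
#' A zero denominator yields `NA` (the "undefined" marker — e.g. PPV is
#' undefined for a category that receives no positive calls), never an
#' error or NaN; [metric_table()] renders these cells as `"x"`.
#'
#' @param confusion A confusion-count tibble from [confusion_counts()].
#' @return The input with columns `sensitivity_pct`, `specificity_pct`,
#'   `ppv_pct`, `npv_pct` appended (unrounded percentages).
#' @export
classification_metrics <- function(confusion) {
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  dplyr::mutate(
    confusion,
    sensitivity_pct = pct(.data$tp, .data$tp + .data$fn),
    specificity_pct = pct(.data$tn, .data$tn + .data$fp),
    ppv_pct = pct(.data$tp, .data$tp + .data$fp),
    npv_pct = pct(.data$tn, .data$tn + .data$fn)
  )
}

#' One-vs-rest ROC curve and AUC
#'
#' The AUC is computed as the Mann–Whitney U statistic on the scores
#' (probability that a random positive outscores a random negative, ties
#' counting 1/2), via average ranks. The curve is built by sweeping every
#' distinct score as a threshold; tied samples enter as a single step, so
#' the trapezoidal integral of the curve equals the U-based AUC exactly.
#' The threshold used for category calling plays no role here: ROC operates
#' on the raw category probability.
#'
#' @param scores Numeric scores (higher = more positive-like); for
#'   eye-colour evaluation, the category's predicted probability.
#' @param is_positive Logical vector, `TRUE` for samples whose observed
#'   phenotype is the category under evaluation.
#' @return A list of class `irisplex_roc`: `auc` (scalar) and `curve`
#'   (tibble `threshold`, `fpr`, `tpr`, starting at (0,0) and ending at
#'   (1,1), both coordinates non-decreasing).
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc # 1
roc_auc <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  if (anyNA(scores) || anyNA(is_positive)) {
    abort("scores and labels must be complete", class = "irisplexr_roc_error")
  }
  is_positive <- as.logical(is_positive)
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs at least one positive and one negative sample",
          class = "irisplexr_roc_error")
  }
  r <- rank(scores) # average ranks give ties weight 1/2
  auc <- (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # curve: one step per distinct score, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- is_positive[ord]
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(pos)[last_of_run]
  fp <- cumsum(!pos)[last_of_run]
  curve <- tibble(
    threshold = c(Inf, s[last_of_run]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  structure(list(auc = auc, curve = curve), class = "irisplex_roc")
}

#' @export
print.irisplex_roc <- function(x, ...) {
  cat("<irisplex_roc> AUC =", format(x$auc, digits = 6),
      "(", nrow(x$curve) - 1, "distinct thresholds )\n")
  invisible(x)
}

#' Evaluate a predicted cohort against observed phenotypes
#'
#' Runs the full accuracy assessment for each of the three categories:
#' confusion counts and sensitivity/specificity/PPV/NPV at the calling
#' threshold (inconclusive-as-negative), plus the one-vs-rest ROC/AUC on
#' the raw category probabilities (threshold-free).
#'
#' @param predictions A [predict_eye_colour()] tibble (or a re-read
#'   prediction report).
#' @param truth Phenotype tibble (`sample_id`, `eye_colour`).
#' @return An object of class `irisplex_eval`: `metrics` (per-category
#'   tibble with counts, percentages and `auc`), `roc` (named list of
#'   `irisplex_roc`), `threshold`, `n`. Use [metric_table()],
#'   [tidy.irisplex_eval()], [autoplot.irisplex_eval()].
#' @export
evaluate_predictions <- function(predictions, truth) {
  dat <- align_by_sample(predictions, truth)
  threshold <- unique(dat$threshold)
  if (length(threshold) != 1) {
    abort("predictions mix calling thresholds", class = "irisplexr_eval_error")
  }
  metrics <- classification_metrics(
    confusion_counts(dat[, c("sample_id", "call")], truth)
  )
  prob_col <- c(blue = "p_blue", intermediate = "p_intermediate", brown = "p_brown")
  roc <- purrr::map(setNames(eye_colours(), eye_colours()), function(cat) {
    roc_auc(dat[[prob_col[[cat]]]], dat$eye_colour == cat)
  })
  metrics$auc <- vapply(metrics$category, function(cat) roc[[cat]]$auc, numeric(1))
  structure(
    list(metrics = metrics, roc = roc, threshold = threshold, n = nrow(dat)),
    class = "irisplex_eval"
  )
}

#' Accuracy report in the conventional layout
#'
#' Formats an evaluation as the conventional forensic accuracy table: one
#' row per parameter (AUC, sensitivity, specificity, PPV, NPV), one column
#' per colour. AUC is displayed to 3 decimals and percentages to 1 decimal;
#' undefined cells (zero denominator, e.g. PPV with no positive calls) are
#' rendered `"x"`. All internal arithmetic is unrounded — rounding here is
#' display-only.
#'
#' @param eval An `irisplex_eval` object.
#' @return A tibble with a `parameter` column and one character column per
#'   category.
#' @export
metric_table <- function(eval) {
  stopifnot(inherits(eval, "irisplex_eval"))
  m <- eval$metrics
  fmt <- function(x, digits) ifelse(is.na(x), "x", formatC(x, format = "f", digits = digits))
  rows <- list(
    c(parameter = "AUC", setNames(fmt(m$auc, 3), m$category)),
    c(parameter = "Sensitivity (%)", setNames(fmt(m$sensitivity_pct, 1), m$category)),
    c(parameter = "Specificity (%)", setNames(fmt(m$specificity_pct, 1), m$category)),
    c(parameter = "Positive predictive value (%)", setNames(fmt(m$ppv_pct, 1), m$category)),
    c(parameter = "Negative predictive value (%)", setNames(fmt(m$npv_pct, 1), m$category))
  )
  dplyr::bind_rows(rows)
}

#' @export
print.irisplex_eval <- function(x, ...) {
  cat("<irisplex_eval> n =", x$n, " threshold =", x$threshold, "\n")
  print(as.data.frame(metric_table(x)), row.names = FALSE)
  invisible(x)
}

#' Tidy and summarise evaluations
#'
#' `tidy()` returns one row per category and metric (long format, unrounded
#' values, `NA` for undefined); `glance()` a one-row summary.
#'
#' @param x An `irisplex_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy irisplex_eval
#' @export
tidy.irisplex_eval <- function(x, ...) {
  tidyr::pivot_longer(
    x$metrics,
    cols = c("auc", "sensitivity_pct", "specificity_pct", "ppv_pct", "npv_pct"),
    names_to = "metric", values_to = "value"
  )[, c("category", "metric", "value", "tp", "fp", "tn", "fn")]
}

#' @rdname tidy.irisplex_eval
#' @method glance irisplex_eval
#' @export
glance.irisplex_eval <- function(x, ...) {
  tibble(
    n = x$n, threshold = x$threshold,
    n_inconclusive = x$n - sum(x$metrics$tp + x$metrics$fp),
    mean_auc = mean(x$metrics$auc)
  )
}

#' Plot one-vs-rest ROC curves
#'
#' @param object An `irisplex_eval` object.
#' @param ... Unused.
#' @return A ggplot: one ROC curve per category with AUC in the legend.
#' @method autoplot irisplex_eval
#' @export
autoplot.irisplex_eval <- function(object, ...) {
  curves <- purrr::map_dfr(eye_colours(), function(cat) {
    dplyr::mutate(object$roc[[cat]]$curve,
                  category = sprintf("%s (AUC %.3f)", cat, object$roc[[cat]]$auc))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  colour = NULL, title = "One-vs-rest ROC") +
    ggplot2::theme_minimal()
}

#' Plot predicted probability triples
#'
#' Stacked per-sample category probabilities ordered by the blue
#' probability, coloured by category, with the calling threshold marked.
#'
#' @param predictions A [predict_eye_colour()] tibble.
#' @return A ggplot.
#' @export
plot_probabilities <- function(predictions) {
  long <- tidyr::pivot_longer(predictions, cols = c("p_blue", "p_intermediate", "p_brown"),
                              names_to = "category", values_to = "probability")
  long$category <- sub("^p_", "", long$category)
  ord <- predictions$sample_id[order(predictions$p_blue, decreasing = TRUE)]
  long$sample_id <- factor(long$sample_id, levels = ord)
  long$category <- factor(long$category, levels = rev(eye_colours()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$probability,
                                     fill = .data$category)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = unique(predictions$threshold),
                        linetype = "dashed", colour = "black") +
    ggplot2::scale_fill_manual(values = c(blue = "#4477AA", intermediate = "#66AA55",
                                          brown = "#8B5A2B")) +
    ggplot2::labs(x = NULL, y = "Predicted probability", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
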