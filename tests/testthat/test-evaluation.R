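# reconstructable cohort-scale confusion fixtures: per-category counts with
# calls laid out explicitly so the tabulation can be cross-checked
make_calls_truth <- function(truth_cats, call_cats) {
  ids <- sprintf("C%04d", seq_along(truth_cats))
  list(calls = tibble::tibble(sample_id = ids, call = call_cats),
       truth = tibble::tibble(sample_id = ids, eye_colour = truth_cats))
}

test_that("confusion counts implement inconclusive-as-negative", {
  # 47 blue truths: 44 called blue, 3 inconclusive; 58 non-blue: 4 called
  # blue, the rest inconclusive/other
  truth <- c(rep("blue", 47), rep("brown", 31), rep("intermediate", 27))
  calls <- c(rep("blue", 44), rep("inconclusive", 3),
             rep("blue", 2), rep("brown", 18), rep("inconclusive", 11),
             rep("blue", 2), rep("inconclusive", 25))
  ct <- make_calls_truth(truth, calls)
  conf <- confusion_counts(ct$calls, ct$truth)
  blue <- conf[conf$category == "blue", ]
  expect_equal(blue$tp, 44)
  expect_equal(blue$fn, 3)
  expect_equal(blue$fp, 4)
  expect_equal(blue$tn, 54)
  # per-category counts always total the cohort
  expect_true(all(conf$tp + conf$fp + conf$tn + conf$fn == 105))
  # tp + fn equals the number of truths in that category
  expect_equal(conf$tp + conf$fn,
               as.vector(table(factor(truth, levels = eye_colours()))))
})

test_that("all-inconclusive calling yields a degenerate all-negative table", {
  truth <- rep(eye_colours(), times = c(5, 3, 4))
  ct <- make_calls_truth(truth, rep("inconclusive", 12))
  conf <- confusion_counts(ct$calls, ct$truth)
  expect_true(all(conf$tp == 0))
  expect_true(all(conf$fp == 0))
  expect_equal(conf$fn, c(5, 3, 4))
  expect_equal(conf$tn, 12 - c(5, 3, 4))
  # and metrics never throw: undefined PPV, zero sensitivity, full specificity
  m <- classification_metrics(conf)
  expect_true(all(is.na(m$ppv_pct)))
  expect_equal(m$sensitivity_pct, c(0, 0, 0))
  expect_equal(m$specificity_pct, c(100, 100, 100))
})

test_that("confusion counts match a naive double-loop tabulation on a random cohort", {
  withr::local_seed(202)
  truth <- sample(eye_colours(), 200, replace = TRUE)
  calls <- sample(c(eye_colours(), "inconclusive"), 200, replace = TRUE)
  ct <- make_calls_truth(truth, calls)
  conf <- confusion_counts(ct$calls, ct$truth)
  for (cat in eye_colours()) {
    tp <- fp <- tn <- fn <- 0
    for (i in 1:200) {
      pos_call <- calls[i] == cat
      pos_true <- truth[i] == cat
      if (pos_call && pos_true) tp <- tp + 1
      else if (pos_call && !pos_true) fp <- fp + 1
      else if (!pos_call && pos_true) fn <- fn + 1
      else tn <- tn + 1
    }
    row <- conf[conf$category == cat, ]
    expect_equal(c(row$tp, row$fp, row$tn, row$fn), c(tp, fp, tn, fn))
  }
})

test_that("metric formulas reproduce the published percentages at display rounding", {
  # confusion counts reconstructed from the published numerators and
  # denominators of the 105-sample study
  conf <- tibble::tibble(
    category = eye_colours(),
    tp = c(44, 0, 18),
    fn = c(3, 27, 13),
    fp = c(4, 0, 8),
    tn = c(54, 78, 66)
  )
  m <- classification_metrics(conf)
  expect_equal(round(m$sensitivity_pct, 1), c(93.6, 0, 58.1))
  expect_equal(round(m$specificity_pct, 1), c(93.1, 100, 89.2))
  expect_equal(round(m$ppv_pct, 1), c(91.7, NA, 69.2))
  expect_equal(round(m$npv_pct, 1), c(94.7, 74.3, 83.5))
  # exact identities behind the display values
  expect_equal(m$sensitivity_pct[1], 100 * 44 / 47, tolerance = 1e-12)
  expect_equal(m$sensitivity_pct[3], 100 * 18 / 31, tolerance = 1e-12)
})

test_that("sample-id misalignment is a hard error naming offenders", {
  ct <- make_calls_truth(rep("blue", 3), rep("blue", 3))
  bad_truth <- ct$truth
  bad_truth$sample_id[2] <- "ZZZ"
  expect_error(confusion_counts(ct$calls, bad_truth), "ZZZ",
               class = "irisplexr_align_error")
})

test_that("AUC handles the perfect and uninformative extremes", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), class = "irisplexr_roc_error")
})

test_that("AUC equals the exhaustive pairwise concordance count", {
  withr::local_seed(303)
  for (rep in 1:20) {
    n <- 30
    scores <- round(stats::runif(n), 2) # rounding forces ties
    labels <- stats::runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    res <- roc_auc(scores, labels)
    pos <- scores[labels]
    neg <- scores[!labels]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(res$auc, mean(pairs), tolerance = 1e-12)
  }
})

test_that("the ROC curve is a valid staircase whose trapezoid equals the AUC", {
  withr::local_seed(404)
  for (rep in 1:10) {
    scores <- round(stats::runif(50), 1)
    labels <- stats::runif(50) < 0.5
    if (!any(labels) || all(labels)) next
    res <- roc_auc(scores, labels)
    cv <- res$curve
    expect_equal(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
    expect_equal(c(cv$fpr[nrow(cv)], cv$tpr[nrow(cv)]), c(1, 1))
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
    trapz <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + cv$tpr[-1]) / 2)
    expect_equal(trapz, res$auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::local_seed(505)
  scores <- stats::runif(80)
  labels <- stats::runif(80) < 0.5
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(stats::qlogis(scores), labels)$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(scores^3 + 10, labels)$auc, base, tolerance = 1e-12)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(606)
  scores <- round(stats::runif(200), 2)
  labels <- stats::runif(200) < 0.45
  own <- roc_auc(scores, labels)$auc
  ext <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        levels = c(FALSE, TRUE),
                                        direction = "<", quiet = TRUE)))
  expect_equal(own, ext, tolerance = 1e-12)
})

test_that("cohort evaluation is deterministic and internally consistent", {
  prm <- make_test_params()
  cfg <- slovenian_cohort_config(n = 500)
  cohort <- simulate_cohort(cfg, seed = 12)
  pred <- predict_eye_colour(cohort$genotypes, prm)
  ev1 <- evaluate_predictions(pred, cohort$phenotypes)
  ev2 <- evaluate_predictions(pred, cohort$phenotypes)
  expect_identical(ev1$metrics, ev2$metrics)
  expect_equal(ev1$n, 500)
  # tp+fn over categories partitions the cohort; positives never exceed it
  expect_equal(sum(ev1$metrics$tp + ev1$metrics$fn), 500)
  expect_lte(sum(ev1$metrics$tp), 500)
  # metric identities hold unrounded
  m <- ev1$metrics
  expect_equal(m$sensitivity_pct, 100 * m$tp / (m$tp + m$fn), tolerance = 1e-8)
  expect_equal(m$specificity_pct, 100 * m$tn / (m$tn + m$fp), tolerance = 1e-8)
})

test_that("arg-max calling (threshold just above 1/3) partitions the cohort into positives", {
  withr::local_seed(19)
  p <- random_probability_triples(300, seed = 19)
  pred <- tibble::tibble(
    sample_id = sprintf("C%04d", 1:300),
    p_blue = p$p_blue, p_intermediate = p$p_intermediate, p_brown = p$p_brown,
    call = call_eye_colour(p$p_blue, p$p_intermediate, p$p_brown, 1 / 3 + 1e-9),
    threshold = 1 / 3 + 1e-9
  )
  truth <- tibble::tibble(sample_id = pred$sample_id,
                          eye_colour = sample(eye_colours(), 300, replace = TRUE))
  ev <- evaluate_predictions(pred, truth)
  expect_equal(sum(ev$metrics$tp + ev$metrics$fp), 300)
})

test_that("the report table mirrors the conventional layout with x for undefined", {
  truth <- rep(eye_colours(), times = c(4, 3, 3))
  p <- tibble::tibble(
    sample_id = sprintf("C%04d", 1:10),
    p_blue = c(rep(0.9, 4), rep(0.2, 6)),
    p_intermediate = c(rep(0.05, 4), rep(0.3, 6)),
    p_brown = c(rep(0.05, 4), rep(0.5, 6)),
    call = c(rep("blue", 4), rep("inconclusive", 6)),
    threshold = 0.7
  )
  ev <- evaluate_predictions(p, tibble::tibble(sample_id = p$sample_id,
                                               eye_colour = truth))
  tab <- metric_table(ev)
  expect_equal(tab$parameter,
               c("AUC", "Sensitivity (%)", "Specificity (%)",
                 "Positive predictive value (%)", "Negative predictive value (%)"))
  expect_equal(names(tab), c("parameter", eye_colours()))
  # no intermediate or brown positive calls -> PPV rendered "x"
  ppv <- tab[tab$parameter == "Positive predictive value (%)", ]
  expect_equal(ppv$intermediate, "x")
  expect_equal(ppv$brown, "x")
  expect_equal(ppv$blue, "100.0")
  # tidy/glance expose unrounded values and the undefined marker as NA
  td <- tidy(ev)
  expect_true(is.na(td$value[td$category == "intermediate" & td$metric == "ppv_pct"]))
  expect_equal(glance(ev)$n, 10)
})

test_that("roc plots and probability plots build without error", {
  prm <- make_test_params()
  cohort <- simulate_cohort(slovenian_cohort_config(n = 80), seed = 3)
  pred <- predict_eye_colour(cohort$genotypes, prm)
  ev <- evaluate_predictions(pred, cohort$phenotypes)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(plot_probabilities(pred), "ggplot")
})
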