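#' One-command end-to-end analysis
#'
#' Runs the whole pipeline on synthetic data: simulate a training cohort
#' with the Slovenian genotype–phenotype structure, fit the
#' multinomial-logistic model on it, simulate an evaluation cohort of 105
#' samples from the same structure, predict and call eye colour at the
#' threshold, and evaluate accuracy (confusion metrics + one-vs-rest
#' ROC/AUC). Also computes the configuration's exact expected composition
#' (see [cohort_expectations()]) as a calibration check.
#'
#' Both cohorts are drawn from the same generator, so this is an internal
#' consistency exercise: it demonstrates the machinery, not out-of-sample
#' accuracy on real irises.
#'
#' @param seed Integer master seed; training, evaluation cohort and any
#'   other draws derive from it deterministically.
#' @param n_train Training cohort size (default 3804, the scale of the
#'   published model's training set).
#' @param threshold Calling threshold (default 0.7).
#' @param out_dir Optional directory; when given, writes `genotypes.csv`,
#'   `phenotypes.csv`, `predictions.csv`, `metrics.csv` and
#'   `expectations.csv` there.
#' @return A list of class `irisplex_study`: `fit`, `cohort`,
#'   `predictions`, `evaluation`, `expectations`, `metric_table`, `seed`.
#' @export
#' @examples
#' \donttest{
#' st <- reproduce_study(seed = 1, n_train = 1000)
#' st$metric_table
#' }
reproduce_study <- function(seed = 1, n_train = 3804, threshold = 0.7,
                            out_dir = NULL) {
  config <- slovenian_cohort_config()
  train_cfg <- config
  train_cfg$n <- n_train
  training <- simulate_cohort(train_cfg, seed = seed)
  fit <- fit_irisplex(training$genotypes, training$phenotypes)
  cohort <- simulate_cohort(config, seed = seed + 1L)
  predictions <- predict_eye_colour(cohort$genotypes, fit$params,
                                    threshold = threshold)
  evaluation <- evaluate_predictions(predictions, cohort$phenotypes)
  expectations <- cohort_expectations(config)
  result <- structure(
    list(fit = fit, cohort = cohort, predictions = predictions,
         evaluation = evaluation, expectations = expectations,
         metric_table = metric_table(evaluation), seed = seed),
    class = "irisplex_study"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genotype_csv(cohort$genotypes, file.path(out_dir, "genotypes.csv"))
    readr::write_csv(cohort$phenotypes, file.path(out_dir, "phenotypes.csv"))
    write_prediction_report(predictions, file.path(out_dir, "predictions.csv"))
    readr::write_csv(result$metric_table, file.path(out_dir, "metrics.csv"))
    exp_tbl <- tibble(
      quantity = c("pct_blue_given_cc", "pct_brown_given_ct", "pct_brown_given_tt",
                   "pct_brown_given_t_carrier", "pct_dark_given_t_carrier",
                   paste0("prevalence_", eye_colours(), "_pct")),
      value = c(expectations$pct_blue_given_cc, expectations$pct_brown_given_ct,
                expectations$pct_brown_given_tt,
                expectations$pct_brown_given_t_carrier,
                expectations$pct_dark_given_t_carrier,
                unname(expectations$prevalence_pct[eye_colours()]))
    )
    readr::write_csv(exp_tbl, file.path(out_dir, "expectations.csv"))
  }
  result
}

#' @export
print.irisplex_study <- function(x, ...) {
  cat("<irisplex_study> seed =", x$seed, " training n =", x$fit$n,
      " evaluation n =", x$evaluation$n, "\n\n")
  print(as.data.frame(x$metric_table), row.names = FALSE)
  inconc <- sum(x$predictions$call == "inconclusive")
  cat("\ninconclusive calls:", inconc, "/", nrow(x$predictions), "\n")
  invisible(x)
}
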