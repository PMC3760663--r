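#' Predict eye-colour probabilities and calls
#'
#' The model is the standard multinomial logistic form. For each
#' non-reference category \eqn{k}, the linear predictor over the six
#' effect-allele dosages \eqn{x_j} is
#' \deqn{\eta_k = \alpha_k + \sum_j \beta_{kj} x_j,}
#' and with the reference category's predictor fixed at 0,
#' \deqn{p_k = e^{\eta_k} / (1 + \sum_m e^{\eta_m}), \quad
#'       p_{ref} = 1 / (1 + \sum_m e^{\eta_m}).}
#' The softmax is evaluated through a log-sum-exp normalisation so linear
#' predictors of magnitude up to several hundred remain stable. Output is
#' always in `(p_blue, p_intermediate, p_brown)` order regardless of the
#' parameter set's internal reference coding.
#'
#' A category is called when its probability is the unique maximum of the
#' triple and reaches the threshold (inclusive: a probability of exactly
#' 0.700 at the default passes); otherwise the call is `"inconclusive"`.
#' Exact arg-max ties at or above threshold — possible only with degenerate
#' parameters — are also inconclusive: a tie is not a supported single-colour
#' prediction.
#'
#' @param genotypes Genotype dosage tibble (`sample_id` + one column per
#'   panel SNP), as returned by [read_genotypes()] or [simulate_cohort()].
#' @param params An `irisplex_params` object.
#' @param threshold Calling threshold in (1/3, 1]; the forensic standard is
#'   0.7.
#' @param missing Missing-dosage policy: `"strict"` (default) refuses any
#'   missing dosage; `"mean_impute"` replaces a missing dosage by twice the
#'   effect-allele frequency (see [impute_missing()]).
#' @param allele_freq Named effect-allele frequencies, required for
#'   `missing = "mean_impute"`.
#' @return A tibble with columns `sample_id`, `p_blue`, `p_intermediate`,
#'   `p_brown`, `call`, `threshold`.
#' @export
#' @examples
#' pn <- irisplex_panel()
#' prm <- read_params(system.file("extdata", "irisplex_params_published.yaml",
#'                                package = "irisplexr"))
#' g <- tibble::tibble(sample_id = "S1", rs12913832 = 0, rs1800407 = 0,
#'                     rs12896399 = 1, rs16891982 = 0, rs1393350 = 1,
#'                     rs12203592 = 0)
#' predict_eye_colour(g, prm)
predict_eye_colour <- function(genotypes, params, threshold = 0.7,
                               missing = c("strict", "mean_impute"),
                               allele_freq = NULL) {
  stopifnot(inherits(params, "irisplex_params"))
  missing <- match.arg(missing)
  rs <- params$panel$rs_id
  absent <- setdiff(rs, names(genotypes))
  if (length(absent) > 0) {
    abort(paste0("genotype table does not match the parameter panel; missing SNP(s): ",
                 paste(absent, collapse = ", ")),
          class = "irisplexr_panel_error")
  }
  genotypes <- impute_missing(genotypes, params$panel, policy = missing,
                              allele_freq = allele_freq)
  x <- as.matrix(genotypes[, rs])
  probs <- softmax_probs(x, params)
  calls <- call_eye_colour(probs[, "blue"], probs[, "intermediate"],
                           probs[, "brown"], threshold = threshold)
  tibble(
    sample_id = genotypes$sample_id,
    p_blue = as.numeric(probs[, "blue"]),
    p_intermediate = as.numeric(probs[, "intermediate"]),
    p_brown = as.numeric(probs[, "brown"]),
    call = calls,
    threshold = threshold
  )
}

# n x 6 dosage matrix -> n x 3 probability matrix, columns in canonical
# order; log-sum-exp guarded softmax.
softmax_probs <- function(x, params) {
  eta <- x %*% t(params$beta)                      # n x 2
  eta <- sweep(eta, 2, params$alpha, "+")
  full <- cbind(0, eta)                            # reference first
  colnames(full) <- c(params$reference, params$categories)
  m <- apply(full, 1, max)
  ex <- exp(full - m)
  p <- ex / rowSums(ex)
  p[, eye_colours(), drop = FALSE]
}

#' Threshold-based category calling
#'
#' Vectorised over samples. See [predict_eye_colour()] for the calling
#' convention (inclusive threshold, ties inconclusive).
#'
#' @param p_blue,p_intermediate,p_brown Probability vectors; each triple
#'   must sum to 1 (tolerance 1e-6).
#' @param threshold Calling threshold in (1/3, 1].
#' @return Character vector of calls, values in
#'   `c("blue", "intermediate", "brown", "inconclusive")`.
#' @export
call_eye_colour <- function(p_blue, p_intermediate, p_brown, threshold = 0.7) {
  if (threshold <= 1/3 || threshold > 1) {
    abort("threshold must lie in (1/3, 1]: at 1/3 or below the arg-max always passes",
          class = "irisplexr_call_error")
  }
  p <- cbind(blue = p_blue, intermediate = p_intermediate, brown = p_brown)
  if (nrow(p) == 0) return(character(0))
  if (any(!is.finite(p)) || any(p < -1e-9) ||
      any(abs(rowSums(p) - 1) > 1e-6)) {
    abort("probability triples must be finite, non-negative and sum to 1",
          class = "irisplexr_call_error")
  }
  pmax_ <- apply(p, 1, max)
  n_at_max <- rowSums(p >= pmax_ - 0) # exact ties only
  winner <- eye_colours()[max.col(p, ties.method = "first")]
  ifelse(pmax_ >= threshold & n_at_max == 1, winner, "inconclusive")
}

#' Missing-dosage policy
#'
#' The default policy is strict: prediction refuses profiles with missing
#' dosages, since the evaluation conventions in this package are defined on
#' complete six-SNP profiles. Mean imputation is opt-in: a missing dosage is
#' replaced by its Hardy–Weinberg expectation, twice the effect-allele
#' frequency, and the affected (sample, SNP) pairs are recorded in the
#' `"imputed"` attribute of the result.
#'
#' @param genotypes Genotype dosage tibble.
#' @param panel SNP panel tibble.
#' @param policy `"strict"` or `"mean_impute"`.
#' @param allele_freq Named numeric of effect-allele frequencies covering
#'   every panel SNP with a missing value; required for `"mean_impute"`.
#' @return The genotype tibble, with missing dosages imputed under
#'   `"mean_impute"`; imputed cells listed in `attr(, "imputed")` (a tibble
#'   with `sample_id`, `rs_id`, `dosage`).
#' @export
impute_missing <- function(genotypes, panel = irisplex_panel(),
                           policy = c("strict", "mean_impute"),
                           allele_freq = NULL) {
  policy <- match.arg(policy)
  rs <- intersect(panel$rs_id, names(genotypes))
  miss <- vapply(rs, function(s) sum(is.na(genotypes[[s]])), numeric(1))
  if (sum(miss) == 0) return(genotypes)
  if (policy == "strict") {
    abort(paste0("missing dosage(s) under strict policy at: ",
                 paste(rs[miss > 0], collapse = ", ")),
          class = "irisplexr_missing_error")
  }
  need <- rs[miss > 0]
  if (is.null(allele_freq) || !all(need %in% names(allele_freq))) {
    abort(paste0("mean_impute requires effect-allele frequencies for: ",
                 paste(setdiff(need, names(allele_freq)), collapse = ", ")),
          class = "irisplexr_missing_error")
  }
  imputed <- list()
  for (s in need) {
    i <- which(is.na(genotypes[[s]]))
    genotypes[[s]][i] <- 2 * allele_freq[[s]]
    imputed[[s]] <- tibble(sample_id = genotypes$sample_id[i], rs_id = s,
                           dosage = genotypes[[s]][i])
  }
  attr(genotypes, "imputed") <- dplyr::bind_rows(imputed)
  genotypes
}
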