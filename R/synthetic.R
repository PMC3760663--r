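#' Cohort simulation configuration
#'
#' A cohort config describes the joint genotype–phenotype structure the
#' simulator draws from: cohort size, category prevalences, the
#' rs12913832 (HERC2) genotype distribution conditional on phenotype —
#' HERC2 is the only marker the simulator couples to phenotype — plus
#' phenotype-independent effect-allele frequencies for the remaining five
#' SNPs, and the proportion of hazel (dark) irises among intermediates per
#' HERC2 genotype (used only for dark-iris summaries).
#'
#' `slovenian_cohort_config()` returns the default configuration,
#' calibrated to a published Slovenian population sample of 105 individuals
#' (47 blue, 27 intermediate, 31 brown). Its HERC2 joint structure encodes,
#' per genotype class: CC carriers 45 blue / 4 intermediate / 0 brown;
#' CT carriers 2 blue / 20 intermediate / 19 brown; TT carriers
#' 0 blue / 3 intermediate / 12 brown — the unique joint table consistent
#' with the published margins and every published conditional proportion
#' (91.8% of CC blue; 46.3% of CT and 80% of TT brown; 55.4% of T-allele
#' carriers brown and 87.5% dark-eyed). The rs1800407 effect-allele (A)
#' frequency is the published 0.119; the remaining four SNP frequencies
#' were not published for this cohort and default to typical European
#' values, flagged `assumed` — tests never assert on them.
#'
#' @param n Cohort size (default 105).
#' @return A list of class `cohort_config` with elements `n`,
#'   `prevalence` (named over categories), `herc2_given_category`
#'   (3x3 matrix, rows = categories, cols = CC/CT/TT),
#'   `hazel_given_intermediate` (named over CC/CT/TT), `snp_freq` (named
#'   effect-allele frequencies for the five non-HERC2 SNPs), `assumed`
#'   (names of frequencies that are assumptions, not published values).
#' @export
#' @examples
#' slovenian_cohort_config()$prevalence
slovenian_cohort_config <- function(n = 105) {
  herc2 <- matrix(
    c(45 / 47, 2 / 47, 0 / 47,    # blue
      4 / 27, 20 / 27, 3 / 27,    # intermediate
      0 / 31, 19 / 31, 12 / 31),  # brown
    nrow = 3, byrow = TRUE,
    dimnames = list(eye_colours(), c("CC", "CT", "TT"))
  )
  cohort_config(
    n = n,
    prevalence = c(blue = 47 / 105, intermediate = 27 / 105, brown = 31 / 105),
    herc2_given_category = herc2,
    hazel_given_intermediate = c(CC = 0, CT = 18 / 20, TT = 0),
    snp_freq = c(rs1800407 = 0.119, rs12896399 = 0.40, rs16891982 = 0.04,
                 rs1393350 = 0.26, rs12203592 = 0.08),
    assumed = c("rs12896399", "rs16891982", "rs1393350", "rs12203592")
  )
}

#' @rdname slovenian_cohort_config
#' @param prevalence Named probabilities over `eye_colours()`.
#' @param herc2_given_category Row-stochastic 3x3 matrix of
#'   P(rs12913832 genotype | category).
#' @param hazel_given_intermediate Named proportions of hazel irises among
#'   intermediates, per HERC2 genotype.
#' @param snp_freq Named effect-allele frequencies for the five non-HERC2
#'   panel SNPs.
#' @param assumed Character vector naming which `snp_freq` entries are
#'   assumptions rather than observed values.
#' @export
cohort_config <- function(n, prevalence, herc2_given_category,
                          hazel_given_intermediate = c(CC = 0, CT = 0, TT = 0),
                          snp_freq, assumed = character(0)) {
  cfg <- structure(
    list(n = n, prevalence = prevalence,
         herc2_given_category = herc2_given_category,
         hazel_given_intermediate = hazel_given_intermediate,
         snp_freq = snp_freq, assumed = assumed),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' @rdname slovenian_cohort_config
#' @param config A `cohort_config` to validate.
#' @export
validate_cohort_config <- function(config) {
  ok_prob <- function(p) all(is.finite(p)) && all(p >= 0) && abs(sum(p) - 1) < 1e-12
  if (!is.numeric(config$n) || length(config$n) != 1 || config$n < 0 ||
      config$n != round(config$n)) {
    abort("n must be a non-negative integer", class = "irisplexr_config_error")
  }
  if (!setequal(names(config$prevalence), eye_colours()) ||
      !ok_prob(config$prevalence)) {
    abort("prevalence must be a probability vector over blue/intermediate/brown summing to 1",
          class = "irisplexr_config_error")
  }
  h <- config$herc2_given_category
  if (!is.matrix(h) || !setequal(rownames(h), eye_colours()) ||
      !identical(colnames(h), c("CC", "CT", "TT")) ||
      !all(apply(h, 1, ok_prob))) {
    abort("herc2_given_category must be a row-stochastic matrix over CC/CT/TT per category",
          class = "irisplexr_config_error")
  }
  fr <- c(config$snp_freq, config$hazel_given_intermediate)
  if (anyNA(fr) || any(fr < 0 | fr > 1)) {
    abort("frequencies and proportions must lie in [0, 1]",
          class = "irisplexr_config_error")
  }
  invisible(config)
}

#' Expected cohort composition implied by a configuration
#'
#' Computes, exactly from the configuration (no simulation), the summary
#' quantities the simulator is calibrated on: category prevalences, the
#' marginal rs12913832 genotype distribution, phenotype proportions
#' conditional on genotype (by Bayes' rule), and the brown / dark-iris
#' proportions among T-allele carriers. For the default Slovenian
#' configuration these reproduce the published cohort description.
#'
#' @param config A `cohort_config`.
#' @return A named list: `prevalence_pct` (named vector),
#'   `herc2_marginal` (expected genotype probabilities),
#'   `expected_genotype_counts` (probabilities times `n`),
#'   `phenotype_given_genotype` (3x3 column-conditioned matrix,
#'   rows = categories, cols = genotypes), `pct_blue_given_cc`,
#'   `pct_brown_given_ct`, `pct_brown_given_tt`,
#'   `pct_brown_given_t_carrier`, `pct_dark_given_t_carrier`.
#' @export
cohort_expectations <- function(config) {
  validate_cohort_config(config)
  prev <- config$prevalence[eye_colours()]
  joint <- config$herc2_given_category[eye_colours(), ] * prev # P(cat, geno)
  marg <- colSums(joint)                                       # P(geno)
  pheno_given_geno <- sweep(joint, 2, marg, "/")
  # dark = brown, or intermediate-hazel; per genotype class
  p_dark_geno <- joint["brown", ] +
    joint["intermediate", ] * config$hazel_given_intermediate[colnames(joint)]
  t_carrier <- c("CT", "TT")
  list(
    prevalence_pct = 100 * prev,
    herc2_marginal = marg,
    expected_genotype_counts = config$n * marg,
    phenotype_given_genotype = pheno_given_geno,
    pct_blue_given_cc = 100 * pheno_given_geno["blue", "CC"],
    pct_brown_given_ct = 100 * pheno_given_geno["brown", "CT"],
    pct_brown_given_tt = 100 * pheno_given_geno["brown", "TT"],
    pct_brown_given_t_carrier = 100 * sum(joint["brown", t_carrier]) / sum(marg[t_carrier]),
    pct_dark_given_t_carrier = 100 * sum(p_dark_geno[t_carrier]) / sum(marg[t_carrier])
  )
}

#' Simulate a genotype–phenotype cohort
#'
#' Sampling scheme: each sample's phenotype category is drawn from the
#' prevalence vector; its rs12913832 genotype from the category-conditional
#' table (effect-allele T dosage: CC = 0, CT = 1, TT = 2); the remaining
#' five SNP dosages independently as Binomial(2, effect-allele frequency),
#' i.e. Hardy–Weinberg within category and no linkage disequilibrium.
#' Intermediates additionally receive a hazel flag (`iris_subtype`) with
#' the genotype-specific hazel proportion. Deterministic given `seed`.
#'
#' @param config A `cohort_config`.
#' @param seed Integer seed; recorded in the result.
#' @param panel SNP panel (used for column order; rs12913832 must carry
#'   effect allele T).
#' @return A list of class `synthetic_cohort`: `genotypes` (dosage tibble),
#'   `phenotypes` (tibble `sample_id`, `eye_colour`, `iris_subtype`),
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(config, seed = 1, panel = irisplex_panel()) {
  validate_cohort_config(config)
  validate_panel(panel)
  n <- config$n
  withr::local_seed(seed)
  cat_draw <- if (n > 0) {
    sample(eye_colours(), n, replace = TRUE, prob = config$prevalence[eye_colours()])
  } else character(0)
  geno_levels <- c("CC", "CT", "TT")
  herc2_geno <- vapply(cat_draw, function(cc) {
    sample(geno_levels, 1, prob = config$herc2_given_category[cc, ])
  }, character(1), USE.NAMES = FALSE)
  herc2_dosage <- match(herc2_geno, geno_levels) - 1 # T count
  ids <- sprintf("S%04d", seq_len(n))
  genotypes <- tibble(sample_id = ids)
  for (rs in panel$rs_id) {
    genotypes[[rs]] <- if (rs == "rs12913832") {
      as.numeric(herc2_dosage)
    } else {
      as.numeric(rbinom(n, 2, config$snp_freq[[rs]]))
    }
  }
  hazel_p <- config$hazel_given_intermediate[herc2_geno]
  is_hazel <- cat_draw == "intermediate" & runif(n) < hazel_p
  subtype <- cat_draw
  subtype[cat_draw == "intermediate"] <- ifelse(is_hazel[cat_draw == "intermediate"],
                                                "hazel", "other_intermediate")
  phenotypes <- tibble(sample_id = ids, eye_colour = cat_draw,
                       iris_subtype = subtype)
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' Simulate a model-consistent training cohort
#'
#' Draws all six SNP dosages independently as Binomial(2, effect-allele
#' frequency) and then draws each sample's phenotype from the category
#' probabilities the given parameter set assigns to its genotype. Used to
#' build large training sets for [fit_irisplex()] (the published model was
#' trained on 3804 individuals, the scale used by the default end-to-end
#' run).
#'
#' @param params An `irisplex_params` generating model.
#' @param allele_freq Named effect-allele frequencies covering every panel
#'   SNP.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A `synthetic_cohort` (with `config = NULL`).
#' @export
simulate_training_cohort <- function(params, allele_freq, n, seed = 1) {
  stopifnot(inherits(params, "irisplex_params"))
  rs <- params$panel$rs_id
  missing_fr <- setdiff(rs, names(allele_freq))
  if (length(missing_fr) > 0) {
    abort(paste0("allele_freq missing for: ", paste(missing_fr, collapse = ", ")),
          class = "irisplexr_config_error")
  }
  if (n < 2 * (nrow(params$panel) + 1)) {
    warn("n is below the model's parameter count; a fit on this cohort will be unstable")
  }
  withr::local_seed(seed)
  ids <- sprintf("T%05d", seq_len(n))
  genotypes <- tibble(sample_id = ids)
  for (s in rs) genotypes[[s]] <- as.numeric(rbinom(n, 2, allele_freq[[s]]))
  probs <- softmax_probs(as.matrix(genotypes[, rs]), params)
  u <- runif(n)
  cum <- t(apply(probs, 1, cumsum))
  idx <- pmin(1 + rowSums(u > cum), 3L)
  phenotypes <- tibble(sample_id = ids, eye_colour = eye_colours()[idx],
                       iris_subtype = eye_colours()[idx])
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 config = NULL, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", nrow(x$genotypes), " seed =", x$seed, "\n")
  print(table(factor(x$phenotypes$eye_colour, levels = eye_colours())))
  invisible(x)
}

#' Typical European effect-allele frequencies for the IrisPlex panel
#'
#' Convenience frequency set for [simulate_training_cohort()] and mean
#' imputation: the Slovenian-calibrated non-HERC2 frequencies of
#' [slovenian_cohort_config()] plus an rs12913832 T frequency implied by
#' that configuration's expected genotype distribution
#' ((P(CT) + 2 P(TT)) / 2).
#'
#' @return Named numeric vector over the six panel SNPs.
#' @export
default_allele_freq <- function() {
  cfg <- slovenian_cohort_config()
  marg <- cohort_expectations(cfg)$herc2_marginal
  c(rs12913832 = unname((marg[["CT"]] + 2 * marg[["TT"]]) / 2), cfg$snp_freq)
}
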