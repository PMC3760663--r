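---
title: "Methods: the IrisPlex model, its evaluation, and the synthetic cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the IrisPlex model, its evaluation, and the synthetic cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irisplexr)
```

## The prediction model

The package implements the multinomial logistic model underlying the
IrisPlex eye-colour system. Each of the six SNPs contributes an
effect-allele dosage $x_j \in \{0,1,2\}$; with a reference category (the
shipped published set uses brown, fits default to blue — the coding is
carried explicitly in every parameter object and is mathematically
irrelevant, see below), the two non-reference categories $k$ get linear
predictors $\eta_k = \alpha_k + \sum_j \beta_{kj} x_j$ and

$$p_k = \frac{e^{\eta_k}}{1 + \sum_m e^{\eta_m}}, \qquad
  p_{\mathrm{ref}} = \frac{1}{1 + \sum_m e^{\eta_m}}.$$

Assumptions inherited from this form: additivity of allele effects on the
log-odds scale (no dominance terms), no SNP×SNP interactions, and a
three-level categorical phenotype. These match how the published model was
built and are why intermediate (green/hazel/mixed) irises — a phenotype
that is genuinely continuous — are poorly separated.

**Reference-category convention.** The multinomial logit is
over-parameterised: shifting all linear predictors by one category's
predictor changes nothing. Parameter files therefore declare their
reference explicitly, all outputs are in fixed
`(p_blue, p_intermediate, p_brown)` order, and `relevel_params()` converts
between codings; a property test verifies predictions are bit-for-bit
invariant (to 1e-12) under relabelling.

**Effect-allele orientation** is data, not code: it lives in the panel file
(`inst/extdata/irisplex_panel.csv`). The shipped orientation counts the
European minor allele at every marker, matching the published model; the
companion coefficient file `irisplex_params_published.yaml` is marked
externally sourced in its provenance field, and no package test depends on
it — all quantitative tests use parameter sets fitted in-package on
synthetic training data.

**Numerical stability.** Probabilities are evaluated through a log-sum-exp
normalisation (subtract the row maximum before exponentiating), so linear
predictors up to magnitude several hundred produce finite, normalised
triples; a test exercises $|\eta| = 700$.

## Calling and its threshold

A colour is called when its probability is the unique arg-max **and**
reaches the threshold; the comparison is inclusive (a probability of
exactly 0.700 is a call at the default threshold), matching the "at or
above 0.7" convention used in forensic validation work. Probabilities are
thresholded unrounded — no display rounding happens before the comparison.
Valid thresholds lie in $(1/3, 1]$: at $1/3$ the arg-max would always pass
and the inconclusive state could never occur, which violates the calling
contract, so that boundary is rejected. Exact arg-max ties at or above
threshold (possible only with degenerate parameters, e.g. two identical
coefficient rows) return inconclusive: a tie is not a supported
single-colour prediction, and this choice is deterministic and
conservative.

**Missing dosages.** The default policy is strict refusal, because the
evaluation conventions are defined on complete six-SNP profiles. Mean
imputation (missing dosage → $2 \times$ effect-allele frequency, the
Hardy–Weinberg expectation) is opt-in, requires explicit frequencies, and
flags every imputed cell in an attribute so reports can disclose it.

## Accuracy evaluation

Evaluation follows the forensic convention in which an inconclusive result
is a negative call for every category: a blue-eyed sample left
inconclusive is a false negative for blue (lowering sensitivity) and a
true negative for brown and intermediate (raising their specificity).
`confusion_counts()` tabulates per-category TP/FP/TN/FN under that rule;
`classification_metrics()` derives sensitivity, specificity, PPV and NPV
as percentages. A zero denominator — e.g. PPV for a category that never
reaches the threshold — yields an explicit undefined marker (`NA`
internally, rendered `x` in the report table), never an exception: this
degenerate case occurs in practice for intermediate eye colour.

ROC analysis deliberately ignores the calling threshold: each category's
curve uses that category's raw predicted probability as the score against
the one-vs-rest truth labels. The AUC is the Mann–Whitney U statistic
computed from average ranks (ties count 1/2), and the curve sweeps every
distinct score as a threshold so tied samples enter as one diagonal step;
this makes the trapezoidal integral of the curve equal the U-statistic
exactly, which the tests assert to 1e-12 against an $O(n^2)$ pairwise
oracle. Display rounding (three decimals for AUC, one for percentages) is
applied only in `metric_table()`; all stored values are unrounded.

## Fitting

`fit_irisplex()` maximises the multinomial log-likelihood by full
Newton–Raphson with analytic gradient and block Hessian, step-halving line
search, deterministic initialisation at zero, at most 200 iterations, and
convergence when the log-likelihood improves by less than 1e-10 or the
gradient infinity-norm drops below 1e-8. Standard errors come from the
inverse observed information at the optimum. The fit is cross-checked in
the test suite against an independent multinomial fitter (`nnet::multinom`)
on the same data, against a coarse-to-fine exhaustive grid search of the
likelihood in a degenerate binary case, and against a parameter-recovery
harness (truth recovered within 3 SE at $n = 50{,}000$).

Quasi-complete separation — a direction of unbounded likelihood increase —
is detected as coefficient divergence (any $|\theta| > 30$, far beyond any
plausible allele effect on the log-odds scale) and raises a typed error
suggesting the ridge option; with `ridge > 0` the fitter maximises a
penalised likelihood instead and flags the result's provenance.
Separation is not hypothetical here: in a 105-sample cohort with the
default Slovenian structure, blue-eyed samples can occur exclusively at
*HERC2* dosage 0, which separates blue almost perfectly, so small-cohort
fits genuinely require the ridge fall-back. The shipped end-to-end run
avoids this by training at $n = 3804$, the scale of the published model's
Dutch training set.

## The synthetic cohort generator

No per-individual genotype–phenotype data are distributed with eye-colour
validation studies, so the package generates cohorts with the published
*statistical structure* instead. The default configuration encodes a
Slovenian population sample of 105 individuals: prevalences 47/105 blue,
27/105 intermediate, 31/105 brown, and an rs12913832 genotype distribution
conditional on phenotype derived from the published joint description.
That source reports the marginal genotype counts (49 CC, 41 CT, 15 TT) and
the conditionals 45/49 CC→blue, 19/41 CT→brown, 12/15 TT→brown, 31/56
T-carriers→brown and 49/56 T-carriers→dark (brown or hazel). Exactly one
joint table is consistent with all of those numbers *and* the phenotype
margins:

| | CC | CT | TT |
|---|---|---|---|
| blue | 45 | 2 | 0 |
| intermediate | 4 | 20 (18 hazel + 2 green) | 3 |
| brown | 0 | 19 | 12 |

In particular, the two CT carriers described as blue with brown
peripupillary rings must sit in the blue margin (otherwise blue totals 45,
not 47, and the dark-iris count cannot reach 49); the package adopts this
reading, and `cohort_expectations()` reproduces every published proportion
exactly from it. The hazel sub-classification matters only for the
dark-iris summary and is tracked as an `iris_subtype` column.

Sampling is: category ~ prevalence; rs12913832 genotype ~ the
category-conditional row; the other five SNP dosages ~ independent
Binomial(2, effect-allele frequency) — Hardy–Weinberg, phenotype-independent,
and with no linkage disequilibrium. Only rs12913832 is coupled to phenotype
because only its joint distribution is published; the rs1800407 A
frequency is the published 11.9%, while the remaining four frequencies
(rs12896399 0.40, rs16891982 0.04, rs1393350 0.26, rs12203592 0.08) are
typical European values chosen once as defaults and flagged `assumed` in
the configuration — no test asserts on them. `simulate_training_cohort()`
instead draws all six SNPs independently and phenotypes from a supplied
parameter set, giving model-consistent training data of arbitrary size.

**What passing tests do and do not show.** Because the generator couples
only *HERC2* to phenotype, cohorts simulated from it carry less predictive
signal than real data: the five minor predictors are pure noise here. The
simulated one-vs-rest AUCs (about 0.95 blue / 0.88 brown / 0.76
intermediate at $n = 10{,}000$) therefore sit slightly below published
real-data values while preserving the qualitative ordering
blue > brown > intermediate, which the acceptance tests check over 20
seeds. Tests that pass on this generator validate the machinery and the
published contingency structure; they do not certify real-world accuracy,
LD structure, population stratification or genotyping error, none of which
are simulated.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`withr::local_seed`),
so every simulation, fit and evaluation is reproducible bit-for-bit. The
test suite uses cohort sizes chosen to make each check statistically sharp
but quick: $n = 100{,}000$ for law-of-large-numbers calibration checks
(3 binomial SEs and a $\chi^2$ goodness-of-fit at $\alpha = 0.001$),
$n = 50{,}000$ for parameter recovery, $n = 20{,}000$ training /
$n = 10{,}000$ evaluation for AUC ordering, and $n = 105$ wherever the
study-scale cohort itself is the object of interest.

## Known limitations

- The shipped published coefficients are a transcription of the published
  model, provided for convenience and marked externally sourced; verify
  them against the original publications before any operational use.
- Intermediate eye colour is structurally hard for this model family; the
  package reproduces that limitation rather than fixing it.
- VCF import matches records by rs ID only; coordinate-based matching,
  liftover and multi-allelic records are out of scope, and strand
  mismatches are a hard error rather than an auto-flip.
- The simulator draws SNPs independently within phenotype; it cannot
  emulate LD, admixture or genotyping error.
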