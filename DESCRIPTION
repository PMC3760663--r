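Package: irisplexr
Title: IrisPlex Eye-Colour Prediction and Accuracy Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forensic DNA phenotyping of human iris colour from the six
    IrisPlex single nucleotide polymorphisms (HERC2 rs12913832, OCA2
    rs1800407, SLC45A2 rs16891982, TYR rs1393350, SLC24A4 rs12896399,
    IRF4 rs12203592). Implements the multinomial logistic prediction of
    blue, intermediate and brown eye-colour probabilities from
    effect-allele dosages, threshold-based category calling with an
    explicit inconclusive state, maximum-likelihood fitting of model
    parameters, and the standard forensic accuracy evaluation
    (sensitivity, specificity, predictive values under an
    inconclusive-as-negative convention, and one-vs-rest ROC/AUC).
    Includes a genotype-phenotype cohort simulator calibrated to a
    published Slovenian population sample so the full
    fit-predict-call-evaluate pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    broom,
    nnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
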