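# Shared fixtures: a hand-set generating parameter set, random genotype
# cohorts, and tiny on-disk genotype files built in code.

test_panel <- function() irisplex_panel()

# Moderate, hand-chosen coefficients (reference = blue) used as the truth
# for parameter-recovery and as a generic non-degenerate model in tests.
make_test_params <- function() {
  pn <- test_panel()
  beta <- rbind(
    intermediate = c(1.0, -0.4, 0.3, -0.6, 0.2, 0.5),
    brown        = c(2.2, -0.8, 0.1, -0.3, 0.4, 0.6)
  )
  colnames(beta) <- pn$rs_id
  irisplex_params("blue", c(intermediate = 0.2, brown = -0.5), beta, pn,
                  provenance = "test fixture")
}

random_genotypes <- function(n, seed = 1, freq = default_allele_freq()) {
  withr::local_seed(seed)
  pn <- test_panel()
  g <- tibble::tibble(sample_id = sprintf("R%04d", seq_len(n)))
  for (s in pn$rs_id) g[[s]] <- as.numeric(stats::rbinom(n, 2, freq[[s]]))
  g
}

# genotype tibble -> minimal VCF 4.2 text (REF = other allele, ALT = effect
# allele, so dosage equals the ALT count)
write_test_vcf <- function(genotypes, path, panel = test_panel()) {
  samples <- genotypes$sample_id
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(panel)), function(i) {
    rs <- panel$rs_id[i]
    gt <- vapply(genotypes[[rs]], function(d) {
      if (is.na(d)) "./." else c("0/0", "0/1", "1/1")[d + 1]
    }, character(1))
    paste(c("15", as.character(1000 + i), rs, panel$other_allele[i],
            panel$effect_allele[i], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# genotype dosages -> allele-pair CSV (e.g. dosage 1 of effect T over C -> "TC")
write_pair_csv <- function(genotypes, path, panel = test_panel()) {
  out <- genotypes["sample_id"]
  for (i in seq_len(nrow(panel))) {
    rs <- panel$rs_id[i]
    e <- panel$effect_allele[i]; o <- panel$other_allele[i]
    out[[rs]] <- vapply(genotypes[[rs]], function(d) {
      if (is.na(d)) "." else paste0(strrep(e, d), strrep(o, 2 - d))
    }, character(1))
  }
  readr::write_csv(out, path)
  invisible(path)
}

random_probability_triples <- function(n, seed = 1) {
  withr::local_seed(seed)
  e <- matrix(stats::rexp(3 * n), ncol = 3)
  p <- e / rowSums(e)
  colnames(p) <- c("p_blue", "p_intermediate", "p_brown")
  tibble::as_tibble(p)
}
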