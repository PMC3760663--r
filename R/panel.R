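#' SNP panel definitions
#'
#' A panel is a tibble with one row per marker and columns `rs_id`, `gene`,
#' `effect_allele` and `other_allele`. The effect allele is the allele whose
#' per-genotype count (dosage 0/1/2) enters the prediction model; its
#' orientation is data, not code, so panels are shipped as editable files.
#'
#' `irisplex_panel()` returns the canonical six-SNP IrisPlex panel. The
#' effect-allele orientation follows the published IrisPlex model (the minor
#' allele in Europeans is counted at every marker); it is stored in
#' `inst/extdata/irisplex_panel.csv` and read from there, so users can supply
#' a re-oriented panel without touching package code.
#'
#' @param path Path to a panel CSV with columns `rs_id`, `gene`,
#'   `effect_allele`, `other_allele`.
#' @return A tibble with columns `rs_id`, `gene`, `effect_allele`,
#'   `other_allele`, one row per SNP, in canonical order.
#' @export
#' @examples
#' irisplex_panel()
irisplex_panel <- function() {
  read_panel(system.file("extdata", "irisplex_panel.csv", package = "irisplexr"))
}

#' @rdname irisplex_panel
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_panel(panel)
  panel
}

#' @rdname irisplex_panel
#' @param panel A panel tibble to validate.
#' @export
validate_panel <- function(panel) {
  required <- c("rs_id", "gene", "effect_allele", "other_allele")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(paste0("panel is missing column(s): ", paste(missing, collapse = ", ")),
          class = "irisplexr_panel_error")
  }
  if (anyDuplicated(panel$rs_id)) {
    abort("panel rs_id values must be unique", class = "irisplexr_panel_error")
  }
  bases <- c("A", "C", "G", "T")
  bad <- !(panel$effect_allele %in% bases) | !(panel$other_allele %in% bases) |
    panel$effect_allele == panel$other_allele
  if (any(bad)) {
    abort(paste0("invalid allele definition for: ",
                 paste(panel$rs_id[bad], collapse = ", "),
                 " (alleles must be distinct single bases A/C/G/T)"),
          class = "irisplexr_panel_error")
  }
  invisible(panel)
}
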