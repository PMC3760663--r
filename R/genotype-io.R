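#' Read genotypes as effect-allele dosages
#'
#' Genotypes are represented throughout the package as a wide tibble with a
#' `sample_id` column and one numeric column per panel SNP holding the
#' effect-allele dosage (0, 1 or 2; `NA` for a no-call). `read_genotypes()`
#' dispatches on the file extension; the format-specific readers can be
#' called directly.
#'
#' The CSV/TSV reader accepts, per cell, either a dosage integer (0/1/2),
#' an unordered two-character allele pair (`"CT"` and `"TC"` are identical;
#' phased `"C|T"` and unphased `"C/T"` separators are also accepted and
#' treated identically, since only the dosage matters), or a missing marker
#' (empty, `"."`, `"NA"`, `"./."`, `".|."`). Columns whose name is not a
#' panel rs id are ignored with a warning.
#'
#' The VCF reader (VCF 4.x via the vcfR package) matches records to the
#' panel by the ID field, never by coordinate — markers are identified by rs
#' number and genome builds are out of scope. GT allele indices are mapped
#' to nucleotides via REF/ALT and then to effect-allele dosage. A panel SNP
#' with no VCF record yields `NA` for every sample.
#'
#' @param path File path (`.vcf` for VCF, anything else is read as
#'   delimited text with the delimiter sniffed from the header line).
#' @param panel SNP panel tibble, see [irisplex_panel()].
#' @return A tibble with columns `sample_id` then one dosage column per
#'   panel SNP, in panel order.
#' @export
read_genotypes <- function(path, panel = irisplex_panel()) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_genotype_vcf(path, panel)
  } else {
    read_genotype_csv(path, panel)
  }
}

#' @rdname read_genotypes
#' @export
read_genotype_csv <- function(path, panel = irisplex_panel()) {
  validate_panel(panel)
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, na = character(),
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE)
  if (!"sample_id" %in% names(raw)) {
    abort("genotype table must contain a `sample_id` column",
          class = "irisplexr_io_error")
  }
  missing_cols <- setdiff(panel$rs_id, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype table is missing required SNP column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "irisplexr_io_error")
  }
  extra <- setdiff(names(raw), c("sample_id", panel$rs_id))
  if (length(extra) > 0) {
    warn(paste0("ignoring non-panel column(s): ", paste(extra, collapse = ", ")))
  }
  out <- tibble(sample_id = raw$sample_id)
  for (i in seq_len(nrow(panel))) {
    rs <- panel$rs_id[i]
    out[[rs]] <- encode_dosage(raw[[rs]], panel$effect_allele[i],
                               panel$other_allele[i], rs)
  }
  out
}

# Convert a character vector of genotype cells to effect-allele dosages.
# Accepts dosage digits, two-base pairs (optionally '/'- or '|'-separated),
# and missing markers.
encode_dosage <- function(x, effect, other, rs_id) {
  x0 <- x
  x <- toupper(trimws(x))
  x <- gsub("[/|]", "", x)
  out <- rep(NA_real_, length(x))
  is_missing <- x %in% c("", ".", "NA", "..")
  is_dosage <- x %in% c("0", "1", "2")
  out[is_dosage] <- as.numeric(x[is_dosage])
  is_pair <- grepl("^[ACGT]{2}$", x)
  if (any(is_pair)) {
    a1 <- substr(x[is_pair], 1, 1)
    a2 <- substr(x[is_pair], 2, 2)
    valid <- a1 %in% c(effect, other) & a2 %in% c(effect, other)
    if (!all(valid)) {
      bad <- which(is_pair)[!valid][1]
      abort(paste0("invalid allele pair \"", x0[bad], "\" for ", rs_id,
                   " (row ", bad, "): expected alleles {", effect, ",", other, "}"),
            class = "irisplexr_io_error")
    }
    out[is_pair] <- (a1 == effect) + (a2 == effect)
  }
  bad <- !(is_missing | is_dosage | is_pair)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("cannot parse genotype \"", x0[i], "\" for ", rs_id,
                 " (row ", i, "): expected a dosage 0/1/2, a two-base pair, or a missing marker"),
          class = "irisplexr_io_error")
  }
  out
}

#' @rdname read_genotypes
#' @export
read_genotype_vcf <- function(path, panel = irisplex_panel()) {
  validate_panel(panel)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) { # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  }
  samples <- colnames(gt)
  if (is.null(samples) || length(samples) == 0) {
    abort("VCF contains no sample genotype columns", class = "irisplexr_io_error")
  }
  out <- tibble(sample_id = samples)
  ids <- fix[, "ID"]
  for (i in seq_len(nrow(panel))) {
    rs <- panel$rs_id[i]
    hit <- which(ids == rs)
    if (length(hit) == 0) {
      out[[rs]] <- NA_real_
      next
    }
    if (length(hit) > 1) {
      abort(paste0("multiple VCF records share ID ", rs), class = "irisplexr_io_error")
    }
    ref <- fix[hit, "REF"]
    alt <- fix[hit, "ALT"]
    if (grepl(",", alt) || nchar(ref) != 1 || nchar(alt) != 1) {
      abort(paste0("record ", rs, " is not a bi-allelic SNP (REF=", ref,
                   ", ALT=", alt, ")"),
            class = "irisplexr_io_error")
    }
    alleles <- c(ref, alt)
    expected <- c(panel$effect_allele[i], panel$other_allele[i])
    if (!all(alleles %in% expected)) {
      abort(paste0("REF/ALT {", ref, ",", alt, "} for ", rs,
                   " do not match panel alleles {", expected[1], ",", expected[2],
                   "}; resolve strand orientation manually before import"),
            class = "irisplexr_io_error")
    }
    out[[rs]] <- gt_to_dosage(gt[hit, ], ref, alt, panel$effect_allele[i], rs)
  }
  out
}

# GT string -> effect-allele dosage; "." anywhere in the call -> NA;
# phased and unphased separators identical.
gt_to_dosage <- function(gt, ref, alt, effect, rs_id) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_real_)
    idx <- strsplit(g, "[/|]")[[1]]
    if (any(idx == ".")) return(NA_real_)
    if (!all(idx %in% c("0", "1")) || length(idx) != 2) {
      abort(paste0("unsupported GT \"", g, "\" at ", rs_id),
            class = "irisplexr_io_error")
    }
    sum(c(ref, alt)[as.integer(idx) + 1] == effect)
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname read_genotypes
#' @param genotypes Genotype dosage tibble to write.
#' @export
write_genotype_csv <- function(genotypes, path) {
  readr::write_csv(genotypes, path)
  invisible(path)
}

#' Read phenotype labels
#'
#' @param path CSV with columns `sample_id` and `eye_colour` (values from
#'   [eye_colours()]).
#' @return A tibble with `sample_id` and `eye_colour`.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample_id", "eye_colour") %in% names(ph))) {
    abort("phenotype table must contain columns sample_id and eye_colour",
          class = "irisplexr_io_error")
  }
  bad <- !(ph$eye_colour %in% eye_colours())
  if (any(bad)) {
    abort(paste0("invalid eye_colour value(s): ",
                 paste(unique(ph$eye_colour[bad]), collapse = ", "),
                 " (expected ", paste(eye_colours(), collapse = "/"), ")"),
          class = "irisplexr_io_error")
  }
  tibble(sample_id = ph$sample_id, eye_colour = ph$eye_colour)
}

#' Write and re-read prediction reports
#'
#' The report is the package's primary output: per sample, the three
#' category probabilities, the thresholded call, and the threshold used.
#' Probabilities are written with enough digits (15 significant) that the
#' file round-trips losslessly and re-thresholding reproduces the calls.
#'
#' @param predictions A prediction tibble as returned by
#'   [predict_eye_colour()]: columns `sample_id`, `p_blue`,
#'   `p_intermediate`, `p_brown`, `call`, `threshold`.
#' @param path Output CSV path.
#' @return `write_prediction_report()` returns `path` invisibly;
#'   `read_prediction_report()` returns the prediction tibble.
#' @export
write_prediction_report <- function(predictions, path) {
  required <- c("sample_id", "p_blue", "p_intermediate", "p_brown", "call", "threshold")
  missing <- setdiff(required, names(predictions))
  if (length(missing) > 0) {
    abort(paste0("prediction report is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "irisplexr_io_error")
  }
  p <- as.matrix(predictions[, c("p_blue", "p_intermediate", "p_brown")])
  if (nrow(predictions) > 0 && !all(is.finite(p))) {
    abort("probabilities must be finite", class = "irisplexr_io_error")
  }
  out <- predictions[, required]
  for (col in c("p_blue", "p_intermediate", "p_brown", "threshold")) {
    out[[col]] <- sprintf("%.15g", out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_prediction_report
#' @export
read_prediction_report <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    p_blue = readr::col_double(),
    p_intermediate = readr::col_double(),
    p_brown = readr::col_double(),
    call = readr::col_character(),
    threshold = readr::col_double()
  ))
}
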