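#' Multinomial-logistic parameter sets
#'
#' An `irisplex_params` object holds the coefficients of the three-category
#' multinomial logistic model: a reference category (linear predictor fixed
#' at zero), and for each of the two non-reference categories an intercept
#' `alpha` plus one effect `beta` per panel SNP, ordered by the panel.
#'
#' Probabilities are invariant to which category plays the reference role
#' when coefficients are transformed consistently (see [relevel_params()]);
#' the reference is therefore carried explicitly so parameter files are
#' self-describing.
#'
#' @param reference Reference category, one of `eye_colours()`.
#' @param alpha Named numeric of length 2: intercepts for the two
#'   non-reference categories.
#' @param beta Numeric matrix, 2 rows (non-reference categories, rownames
#'   required) by `nrow(panel)` columns (colnames = panel `rs_id`).
#' @param panel A SNP panel tibble (see [irisplex_panel()]).
#' @param provenance Free-text tag recording where the values came from.
#' @return An object of class `irisplex_params`.
#' @export
#' @examples
#' pn <- irisplex_panel()
#' b <- matrix(0, 2, 6, dimnames = list(c("intermediate", "brown"), pn$rs_id))
#' irisplex_params("blue", c(intermediate = 0, brown = 0), b, pn, "null model")
irisplex_params <- function(reference, alpha, beta, panel, provenance = "unspecified") {
  validate_panel(panel)
  reference <- match.arg(reference, eye_colours())
  non_ref <- setdiff(eye_colours(), reference)
  if (!is.numeric(alpha) || length(alpha) != 2 || is.null(names(alpha)) ||
      !setequal(names(alpha), non_ref)) {
    abort(paste0("alpha must be a named numeric of length 2 with names {",
                 paste(non_ref, collapse = ", "), "}"),
          class = "irisplexr_params_error")
  }
  if (!is.matrix(beta) || nrow(beta) != 2 || ncol(beta) != nrow(panel) ||
      is.null(rownames(beta)) || !setequal(rownames(beta), non_ref) ||
      is.null(colnames(beta)) || !identical(colnames(beta), panel$rs_id)) {
    abort("beta must be a 2 x n_snp matrix with non-reference-category rownames and panel rs_id colnames (panel order)",
          class = "irisplexr_params_error")
  }
  alpha <- alpha[non_ref]
  beta <- beta[non_ref, , drop = FALSE]
  if (!all(is.finite(alpha)) || !all(is.finite(beta))) {
    abort("all coefficients must be finite", class = "irisplexr_params_error")
  }
  structure(
    list(reference = reference, categories = non_ref,
         alpha = alpha, beta = beta, panel = panel, provenance = provenance),
    class = "irisplex_params"
  )
}

#' @export
print.irisplex_params <- function(x, ...) {
  cat("<irisplex_params>", nrow(x$panel), "SNPs, reference =", x$reference, "\n")
  cat("provenance:", x$provenance, "\n")
  tab <- cbind(`(intercept)` = x$alpha, x$beta)
  print(round(tab, 4))
  invisible(x)
}

#' Re-express a parameter set with a different reference category
#'
#' The multinomial-logistic model is over-parameterised: subtracting one
#' category's linear predictor from all categories leaves every probability
#' unchanged. `relevel_params()` applies that transformation so the same
#' model is expressed relative to a different reference category.
#'
#' @param params An `irisplex_params` object.
#' @param reference The new reference category.
#' @return An `irisplex_params` object describing the identical model.
#' @export
relevel_params <- function(params, reference) {
  stopifnot(inherits(params, "irisplex_params"))
  reference <- match.arg(reference, eye_colours())
  if (reference == params$reference) return(params)
  # full coefficient table incl. current reference row of zeros
  full_a <- c(setNames(0, params$reference), params$alpha)[eye_colours()]
  full_b <- rbind(matrix(0, 1, ncol(params$beta),
                         dimnames = list(params$reference, colnames(params$beta))),
                  params$beta)[eye_colours(), , drop = FALSE]
  non_ref <- setdiff(eye_colours(), reference)
  irisplex_params(
    reference = reference,
    alpha = setNames(full_a[non_ref] - full_a[reference], non_ref),
    beta = sweep(full_b[non_ref, , drop = FALSE], 2, full_b[reference, ], "-"),
    panel = params$panel,
    provenance = paste0(params$provenance, " (releveled to ", reference, ")")
  )
}

#' Read and write parameter files
#'
#' Parameter sets are stored as human-editable YAML with a version tag
#' (`format: irisplex_params/1`): the reference category, the panel (with
#' effect-allele orientation), and per non-reference category an intercept
#' plus one coefficient per rs id.
#'
#' The file shipped at
#' `system.file("extdata", "irisplex_params_published.yaml", package = "irisplexr")`
#' carries the externally sourced published IrisPlex coefficients; see its
#' `provenance` field.
#'
#' @param path File path.
#' @param params An `irisplex_params` object.
#' @return `read_params()` returns an `irisplex_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$format) || !identical(raw$format, "irisplex_params/1")) {
    abort("not an irisplex_params/1 file (missing or unknown `format` tag)",
          class = "irisplexr_params_error")
  }
  panel <- dplyr::bind_rows(lapply(raw$panel, as_tibble))
  validate_panel(panel)
  non_ref <- setdiff(eye_colours(), raw$reference)
  co <- raw$coefficients
  if (!setequal(names(co), non_ref)) {
    abort("coefficients must be given for exactly the two non-reference categories",
          class = "irisplexr_params_error")
  }
  alpha <- vapply(non_ref, function(k) as.numeric(co[[k]][["intercept"]]), numeric(1))
  beta <- t(vapply(non_ref,
                   function(k) vapply(panel$rs_id, function(s) as.numeric(co[[k]][[s]]), numeric(1)),
                   numeric(nrow(panel))))
  dimnames(beta) <- list(non_ref, panel$rs_id)
  irisplex_params(raw$reference, setNames(alpha, non_ref), beta, panel,
                  provenance = raw$provenance %||% "unspecified")
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "irisplex_params"))
  co <- lapply(params$categories, function(k) {
    c(list(intercept = unname(params$alpha[k])),
      as.list(setNames(unname(params$beta[k, ]), colnames(params$beta))))
  })
  names(co) <- params$categories
  out <- list(
    format = "irisplex_params/1",
    reference = params$reference,
    provenance = params$provenance,
    panel = lapply(seq_len(nrow(params$panel)), function(i) as.list(params$panel[i, ])),
    coefficients = co
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
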