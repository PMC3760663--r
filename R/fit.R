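#' Fit the multinomial-logistic eye-colour model
#'
#' Maximum-likelihood fitting of the three-category multinomial logistic
#' model by Newton–Raphson on the full log-likelihood (the iteratively
#' reweighted least squares scheme for this family), with step-halving.
#' Initialisation is at zero, so the fit is deterministic given the data.
#' Convergence is declared when the log-likelihood improves by less than
#' `tol_loglik` or the gradient infinity-norm falls below `tol_grad`.
#'
#' Quasi-complete separation (a direction in which the likelihood increases
#' without bound) manifests as diverging coefficients; the fitter detects
#' this and either aborts or, when `ridge > 0`, maximises a ridge-penalised
#' likelihood instead and flags the result's provenance.
#'
#' @param genotypes Genotype dosage tibble (`sample_id` + one complete
#'   dosage column per panel SNP).
#' @param phenotypes Phenotype tibble (`sample_id`, `eye_colour`); every
#'   category must be observed at least once.
#' @param panel SNP panel tibble.
#' @param reference Reference category for the returned parameter set.
#' @param ridge Ridge penalty (0 = plain MLE) applied to all coefficients
#'   except when 0; used to stabilise separated fits.
#' @param max_iter,tol_loglik,tol_grad Optimiser controls.
#' @return An object of class `irisplex_fit`: a list with elements
#'   `params` (an [irisplex_params()] object usable by
#'   [predict_eye_colour()]), `coefficients` (tidy tibble with standard
#'   errors), `loglik`, `n`, `iterations`, `converged`, `vcov`.
#' @export
fit_irisplex <- function(genotypes, phenotypes, panel = irisplex_panel(),
                         reference = "blue", ridge = 0, max_iter = 200,
                         tol_loglik = 1e-10, tol_grad = 1e-8) {
  validate_panel(panel)
  reference <- match.arg(reference, eye_colours())
  dat <- dplyr::inner_join(genotypes, phenotypes, by = "sample_id")
  if (nrow(dat) < nrow(genotypes) || nrow(dat) < nrow(phenotypes)) {
    abort("genotype and phenotype tables do not share identical sample_ids",
          class = "irisplexr_io_error")
  }
  obs <- table(factor(dat$eye_colour, levels = eye_colours()))
  if (any(obs == 0)) {
    abort(paste0("every category needs at least one sample; missing: ",
                 paste(names(obs)[obs == 0], collapse = ", ")),
          class = "irisplexr_fit_error")
  }
  x <- as.matrix(dat[, panel$rs_id])
  if (anyNA(x)) {
    abort("fitting requires complete dosages (apply a missing-data policy first)",
          class = "irisplexr_missing_error")
  }
  X <- cbind(`(intercept)` = 1, x)
  if (nrow(X) < ncol(X) * 2) {
    warn("fewer samples than twice the parameter count; the fit may be unstable")
  }
  non_ref <- setdiff(eye_colours(), reference)
  y <- vapply(non_ref, function(k) as.numeric(dat$eye_colour == k),
              numeric(nrow(dat)))
  fit <- multinom_mle(X, y, ridge = ridge, max_iter = max_iter,
                      tol_loglik = tol_loglik, tol_grad = tol_grad)
  theta <- fit$theta # p x 2
  alpha <- setNames(theta[1, ], non_ref)
  beta <- t(theta[-1, , drop = FALSE])
  dimnames(beta) <- list(non_ref, panel$rs_id)
  prov <- paste0("fitted by irisplexr (n = ", nrow(dat), ", reference = ",
                 reference, if (fit$ridged) ", ridge-stabilised" else "", ")")
  params <- irisplex_params(reference, alpha, beta, panel, provenance = prov)
  term_names <- c("(intercept)", panel$rs_id)
  coef_tbl <- tibble(
    category = rep(non_ref, each = length(term_names)),
    term = rep(term_names, times = 2),
    estimate = c(theta[, 1], theta[, 2]),
    std_error = c(fit$se[, 1], fit$se[, 2])
  )
  structure(
    list(params = params, coefficients = coef_tbl, loglik = fit$loglik,
         n = nrow(dat), iterations = fit$iterations, converged = fit$converged,
         ridged = fit$ridged, vcov = fit$vcov, reference = reference),
    class = "irisplex_fit"
  )
}

# Newton-Raphson MLE for a K-category multinomial logit with reference
# coded first. X: n x p design; y: n x (K-1) indicator matrix of
# non-reference categories. Returns theta (p x (K-1)), per-coefficient SEs,
# vcov of vec(theta), log-likelihood.
multinom_mle <- function(X, y, ridge = 0, max_iter = 200,
                         tol_loglik = 1e-10, tol_grad = 1e-8) {
  n <- nrow(X); p <- ncol(X); K1 <- ncol(y)
  theta <- matrix(0, p, K1)
  loglik <- function(th) {
    eta <- X %*% th
    m <- pmax(0, apply(eta, 1, max))
    lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum(rowSums(y * eta) - lse) - ridge / 2 * sum(th^2)
  }
  probs <- function(th) {
    eta <- X %*% th
    m <- pmax(0, apply(eta, 1, max))
    ex <- exp(eta - m)
    ex / (exp(-m) + rowSums(ex)) # n x K1 non-reference probabilities
  }
  ll <- loglik(theta)
  converged <- FALSE
  iter <- 0
  gnorm <- Inf
  for (iter in seq_len(max_iter)) {
    P <- probs(theta)
    grad <- as.vector(t(X) %*% (y - P)) - ridge * as.vector(theta)
    gnorm <- max(abs(grad))
    if (gnorm < tol_grad) { converged <- TRUE; break }
    # block Hessian of the negative log-likelihood
    H <- matrix(0, p * K1, p * K1)
    for (k in seq_len(K1)) {
      for (l in seq_len(K1)) {
        w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
        H[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
          t(X) %*% (X * w)
      }
    }
    diag(H) <- diag(H) + ridge
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      abort("singular information matrix: data may be separated or collinear (consider ridge > 0)",
            class = "irisplexr_fit_error")
    }
    # step-halving line search
    new_theta <- theta + matrix(step, p, K1)
    new_ll <- loglik(new_theta)
    halvings <- 0
    while (!is.finite(new_ll) || new_ll < ll) {
      step <- step / 2
      new_theta <- theta + matrix(step, p, K1)
      new_ll <- loglik(new_theta)
      halvings <- halvings + 1
      if (halvings > 50) break
    }
    improvement <- new_ll - ll
    theta <- new_theta
    ll <- new_ll
    if (ridge == 0 && max(abs(theta)) > 30) {
      abort(paste0("coefficients diverging (|theta| > 30): quasi-complete separation suspected; ",
                   "refit with ridge > 0 for a stabilised estimate"),
            class = "irisplexr_separation_error")
    }
    if (improvement < tol_loglik) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(paste0("fit did not converge in ", max_iter,
                 " iterations (last gradient max |g| = ", signif(gnorm, 3), ")"),
          class = "irisplexr_fit_error")
  }
  # observed information at the optimum for standard errors
  P <- probs(theta)
  H <- matrix(0, p * K1, p * K1)
  for (k in seq_len(K1)) {
    for (l in seq_len(K1)) {
      w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      H[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <- t(X) %*% (X * w)
    }
  }
  diag(H) <- diag(H) + ridge
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p * K1, p * K1))
  se <- matrix(sqrt(pmax(diag(vc), 0)), p, K1)
  list(theta = theta, se = se, vcov = vc, loglik = ll, iterations = iter,
       converged = converged, ridged = ridge > 0)
}

#' @export
print.irisplex_fit <- function(x, ...) {
  cat("<irisplex_fit> n =", x$n, " logLik =", format(x$loglik, digits = 8),
      " iterations =", x$iterations,
      if (x$ridged) " (ridge-stabilised)" else "", "\n")
  print(x$params)
  invisible(x)
}

#' @export
coef.irisplex_fit <- function(object, ...) object$params

#' Tidy and summarise fitted models
#'
#' `tidy()` returns one row per coefficient with its standard error;
#' `glance()` returns a one-row model summary.
#'
#' @param x An `irisplex_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy irisplex_fit
#' @export
tidy.irisplex_fit <- function(x, ...) x$coefficients

#' @rdname tidy.irisplex_fit
#' @method glance irisplex_fit
#' @export
glance.irisplex_fit <- function(x, ...) {
  tibble(n = x$n, logLik = x$loglik, df = nrow(x$coefficients),
         iterations = x$iterations, converged = x$converged,
         ridged = x$ridged, reference = x$reference)
}
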