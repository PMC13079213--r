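#' Specify one logistic regression model
#'
#' @param outcome Name of the binary outcome column.
#' @param exposures Character vector of exposure column names entered as main
#'   effects (e.g. `"prs_scz_high"`, `"any_ace"`, `"ace_count"`).
#' @param interaction_terms List of length-2 character vectors; each pair
#'   must be a subset of `exposures` and adds a product term.
#' @param covariates Character vector of adjustment columns. Factor columns
#'   enter as unordered indicator terms, numeric columns linearly.
#' @param extra_product_terms List of length-2 character vectors of
#'   covariate x exposure products (sensitivity adjustment so covariates
#'   cannot masquerade as gene-environment interaction).
#' @return A list of class `psygxe_model_spec`.
#' @export
model_spec <- function(outcome, exposures, interaction_terms = list(),
                       covariates = character(), extra_product_terms = list()) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(exposures), length(exposures) >= 1L)
  for (pair in interaction_terms) {
    if (length(pair) != 2L || !all(pair %in% exposures))
      stop_field("interaction_terms",
                 "each pair must name two included exposures")
  }
  for (pair in extra_product_terms)
    if (length(pair) != 2L)
      stop_field("extra_product_terms", "each element must be a pair of columns")
  structure(list(outcome = outcome, exposures = exposures,
                 interaction_terms = interaction_terms,
                 covariates = covariates,
                 extra_product_terms = extra_product_terms),
            class = "psygxe_model_spec")
}

#' Default covariate set for adjusted models
#'
#' Sex, birth year, employment, income, smoking, education, deprivation
#' index, and the first `n_gpc` genetic principal components.
#'
#' @param n_gpc Number of genetic principal components to adjust for.
#' @return Character vector of column names.
#' @export
default_covariates <- function(n_gpc = 10L) {
  c("sex", "birth_year", "employment", "income", "smoking", "education",
    "imd", paste0("gpc", seq_len(n_gpc)))
}

spec_formula <- function(spec) {
  terms <- c(spec$exposures,
             vapply(spec$interaction_terms, paste, "", collapse = ":"),
             spec$covariates,
             vapply(spec$extra_product_terms, paste, "", collapse = ":"))
  as.formula(paste(spec$outcome, "~", paste(terms, collapse = " + ")),
             env = baseenv())
}

#' Fit one logistic regression model
#'
#' Maximum-likelihood logistic regression on the complete cases for the
#' model's columns (listwise deletion per model, so each phenotype uses every
#' participant with full information for *that* model). Convergence follows
#' iteratively reweighted least squares to a relative deviance change below
#' 1e-8 within 100 iterations. Fits that fail to converge, or whose
#' non-intercept coefficients diverge beyond 15 on the log-odds scale
#' (quasi-complete separation), are flagged; flagged estimates must not be
#' consumed downstream and [tidy_fit()] emits no rows for them.
#'
#' @param cohort A cohort table containing all model columns.
#' @param spec A [model_spec()].
#' @return A list of class `psygxe_fit`: `term`, `beta`, `se`, `p`
#'   (two-sided Wald), `vcov`, `n_used`, `converged`, `separation_flag`,
#'   `spec`.
#' @export
fit_logistic <- function(cohort, spec) {
  if (!inherits(spec, "psygxe_model_spec"))
    stop("`spec` must be built by model_spec()", call. = FALSE)
  prods <- unique(unlist(c(spec$interaction_terms, spec$extra_product_terms)))
  cols <- unique(c(spec$outcome, spec$exposures, spec$covariates, prods))
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("model columns not in cohort: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- cohort[cols]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  y <- dat[[spec$outcome]]
  if (length(unique(y)) < 2L)
    stop("outcome `", spec$outcome, "` has a single level among complete cases",
         call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("outcome `", spec$outcome, "` must be binary 0/1", call. = FALSE)

  fit <- withCallingHandlers(
    glm(spec_formula(spec), family = binomial(), data = dat,
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      # separation surfaces as diverging coefficients, checked below
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  beta <- coef(fit)
  vc <- vcov(fit)
  non_int <- setdiff(names(beta), "(Intercept)")
  diverged <- any(abs(beta[non_int]) > 15, na.rm = TRUE)
  separation <- !fit$converged || diverged || anyNA(beta)
  se <- sqrt(pmax(diag(vc), 0))
  structure(list(term = names(beta), beta = unname(beta), se = unname(se),
                 p = unname(2 * pnorm(-abs(beta / se))),
                 vcov = vc, n_used = nrow(dat),
                 converged = fit$converged,
                 separation_flag = separation,
                 spec = spec),
            class = "psygxe_fit")
}

#' Tidy a logistic fit into a coefficient table
#'
#' @param fit A `psygxe_fit` from [fit_logistic()].
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return A tibble with one row per term: `term`, `beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`, `n`. Flagged (non-converged or separated)
#'   fits yield zero rows: their estimates are unavailable.
#' @export
tidy_fit <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "psygxe_fit"))
  if (fit$separation_flag)
    return(tibble::tibble(term = character(), beta = double(), se = double(),
                          or = double(), ci_low = double(), ci_high = double(),
                          p = double(), n = integer()))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(term = fit$term, beta = fit$beta, se = fit$se,
                 or = exp(fit$beta),
                 ci_low = exp(fit$beta - z * fit$se),
                 ci_high = exp(fit$beta + z * fit$se),
                 p = fit$p, n = fit$n_used)
}

#' @export
print.psygxe_fit <- function(x, ...) {
  cat(sprintf("<psygxe_fit> %s ~ %s | n = %d%s\n",
              x$spec$outcome, paste(x$spec$exposures, collapse = " + "),
              x$n_used,
              if (x$separation_flag) " [FLAGGED: separation/non-convergence]" else ""))
  if (!x$separation_flag) print(tidy_fit(x), ...)
  invisible(x)
}
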