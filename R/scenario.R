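#' Specify the per-disorder threshold-score block of a simulation scenario
#'
#' Raw polygenic scores are simulated at several GWAS p-value thresholds per
#' disorder as a multivariate normal with exchangeable (compound-symmetry)
#' inter-column correlation, then given per-column affine distortions so the
#' columns differ in location and scale the way raw per-threshold scores do.
#' Under compound symmetry with correlation \eqn{\rho} over \eqn{m} columns,
#' the leading eigenvalue share of the correlation matrix is
#' \eqn{(1 + (m-1)\rho)/m}; `pc1_variance_target` may be supplied instead of
#' the correlation and is inverted through that identity.
#'
#' @param n_thresholds Number of p-value thresholds (columns). Default 10.
#' @param inter_threshold_correlation Exchangeable correlation between
#'   threshold columns, in (0, 1]. Ignored if `pc1_variance_target` is given.
#' @param pc1_variance_target Optional target share of variance on the first
#'   principal component, in (0, 1].
#' @return A list of class `psygxe_prs_spec`.
#' @export
prs_component_spec <- function(n_thresholds = 10L,
                               inter_threshold_correlation = 0.85,
                               pc1_variance_target = NULL) {
  m <- as.integer(n_thresholds)
  if (is.na(m) || m < 2L) stop_field("n_thresholds", "must be an integer >= 2")
  if (!is.null(pc1_variance_target)) {
    v <- pc1_variance_target
    if (!is.numeric(v) || length(v) != 1L || v <= 1 / m || v > 1)
      stop_field("pc1_variance_target", sprintf("must lie in (1/%d, 1]", m))
    inter_threshold_correlation <- (m * v - 1) / (m - 1)
  }
  rho <- inter_threshold_correlation
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1)
    stop_field("inter_threshold_correlation", "must lie in (0, 1]")
  structure(list(n_thresholds = m, inter_threshold_correlation = rho),
            class = "psygxe_prs_spec")
}

#' Specify the adversity-item block of a simulation scenario
#'
#' Five ordinal Childhood Trauma Screener items are simulated through a
#' Gaussian copula with exchangeable latent correlation. Endorsement for the
#' three abuse items means responding "Sometimes true" or above; for the two
#' neglect items ("felt loved", "taken to doctor") it means responding
#' "Never true" or "Rarely true".
#'
#' @param endorsement Named numeric of length 5 giving per-item endorsement
#'   probabilities for `physical_abuse`, `emotional_abuse`, `sexual_abuse`,
#'   `emotional_neglect`, `physical_neglect`, each in (0, 1).
#' @param item_correlation Latent exchangeable correlation in [0, 1).
#' @param missing_rate Per-item missing-completely-at-random rate in [0, 1).
#' @return A list of class `psygxe_ace_spec`.
#' @export
ace_spec <- function(endorsement = c(physical_abuse = 0.08,
                                     emotional_abuse = 0.13,
                                     sexual_abuse = 0.05,
                                     emotional_neglect = 0.16,
                                     physical_neglect = 0.06),
                     item_correlation = 0.3,
                     missing_rate = 0) {
  if (!all(ace_item_names() %in% names(endorsement)))
    stop_field("endorsement", paste("must name all of:",
                                    paste(ace_item_names(), collapse = ", ")))
  endorsement <- endorsement[ace_item_names()]
  check_prob(endorsement, "endorsement")
  r <- item_correlation
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r >= 1)
    stop_field("item_correlation", "must lie in [0, 1)")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop_field("missing_rate", "must lie in [0, 1)")
  structure(list(endorsement = endorsement, item_correlation = r,
                 missing_rate = missing_rate),
            class = "psygxe_ace_spec")
}

ace_item_names <- function() {
  c("physical_abuse", "emotional_abuse", "sexual_abuse",
    "emotional_neglect", "physical_neglect")
}

#' Specify the covariate block of a simulation scenario
#'
#' @param p_male Probability of male sex.
#' @param birth_year_mean,birth_year_sd Normal parameters for birth year
#'   (rounded to whole years).
#' @param n_gpc Number of genetic principal components (standard normal).
#' @param n_levels Named integer vector giving the number of levels for each
#'   ordinal covariate (employment, income, smoking, education).
#' @return A list of class `psygxe_covariate_spec`.
#' @export
covariate_spec <- function(p_male = 0.44,
                           birth_year_mean = 1953, birth_year_sd = 8,
                           n_gpc = 10L,
                           n_levels = c(employment = 4L, income = 5L,
                                        smoking = 3L, education = 4L)) {
  check_prob(p_male, "p_male")
  if (!is.numeric(birth_year_sd) || birth_year_sd <= 0)
    stop_field("birth_year_sd", "must be positive")
  n_gpc <- as.integer(n_gpc)
  if (is.na(n_gpc) || n_gpc < 1L) stop_field("n_gpc", "must be a positive integer")
  need <- c("employment", "income", "smoking", "education")
  if (!all(need %in% names(n_levels)))
    stop_field("n_levels", paste("must name", paste(need, collapse = ", ")))
  structure(list(p_male = p_male, birth_year_mean = birth_year_mean,
                 birth_year_sd = birth_year_sd, n_gpc = n_gpc,
                 n_levels = vapply(n_levels[need], as.integer, integer(1))),
            class = "psygxe_covariate_spec")
}

#' Specify one simulated binary (or continuous) phenotype
#'
#' Binary symptoms are drawn from a Bernoulli whose logit is a planted linear
#' predictor over the *dichotomized* exposures that the analysis pipeline
#' reconstructs downstream: high PRS (top quartile of the PRS-PCA score) and
#' any-ACE. The interaction may be planted on the multiplicative scale (the
#' value is the product-term log-odds coefficient directly) or on the
#' additive scale (the value is a target RERI, inverted into a product-term
#' coefficient by [plant_additive_interaction()]).
#'
#' Continuous phenotypes (used for cognition test scores, dichotomized
#' downstream at an impairment quantile) are standard normal minus the same
#' exposure linear predictor, so positive planted effects lower the score.
#'
#' @param prevalence Baseline (reference-group) prevalence in (0, 1); the
#'   intercept of the planted logistic model is `qlogis(prevalence)`.
#' @param prs Which disorder's PRS drives this phenotype: `"scz"` or `"bip"`.
#' @param beta_prs,beta_ace Main-effect log odds ratios of high PRS and any
#'   ACE.
#' @param interaction List with `scale` (`"multiplicative"` or `"additive"`)
#'   and `value` (a log-OR coefficient, or a target RERI respectively).
#' @param covariate_betas Optional named numeric of log-OR per unit of
#'   numeric cohort columns (e.g. `gpc1`, `imd`).
#' @param ace_term Which derived adversity variable carries `beta_ace`:
#'   `"any"` (the binary any-ACE flag, the default and the exposure the main
#'   analysis dichotomizes to), `"count"` (log-OR per additional ACE,
#'   for dose-response scenarios), or one of the five type flags
#'   (`"physical_abuse"`, ..., `"physical_neglect"`). Interactions are only
#'   planted against the binary `"any"` exposure.
#' @param type `"binary"` or `"continuous"`.
#' @return A list of class `psygxe_outcome_spec`.
#' @export
outcome_spec <- function(prevalence = 0.2, prs = c("scz", "bip"),
                         beta_prs = 0, beta_ace = 0,
                         interaction = list(scale = "multiplicative", value = 0),
                         covariate_betas = NULL,
                         ace_term = c("any", "count", ace_item_names()),
                         type = c("binary", "continuous")) {
  type <- match.arg(type)
  prs <- match.arg(prs)
  ace_term <- match.arg(ace_term)
  if (ace_term != "any" && interaction$value != 0)
    stop_field("ace_term", "interactions can only be planted on the binary `any` exposure")
  if (type == "binary") check_prob(prevalence, "prevalence")
  if (!is.list(interaction) || !all(c("scale", "value") %in% names(interaction)))
    stop_field("interaction", "must be a list with elements `scale` and `value`")
  if (!interaction$scale %in% c("multiplicative", "additive"))
    stop_field("interaction$scale", "must be \"multiplicative\" or \"additive\"")
  beta3 <- if (interaction$scale == "additive") {
    plant_additive_interaction(beta_prs, beta_ace, interaction$value)
  } else {
    interaction$value
  }
  structure(list(prevalence = prevalence, prs = prs,
                 beta_prs = beta_prs, beta_ace = beta_ace,
                 interaction = interaction, beta_interaction = beta3,
                 covariate_betas = covariate_betas, ace_term = ace_term,
                 type = type),
            class = "psygxe_outcome_spec")
}

#' Invert the RERI definition to plant an additive interaction
#'
#' The relative excess risk due to interaction for binary exposures is
#' \deqn{RERI = OR_{11} - OR_{10} - OR_{01} + 1}
#' with \eqn{OR_{10} = e^{\beta_1}}, \eqn{OR_{01} = e^{\beta_2}},
#' \eqn{OR_{11} = e^{\beta_1+\beta_2+\beta_3}}. Given the two main-effect
#' log-ORs and a target RERI, this solves for the product-term coefficient
#' \deqn{\beta_3 = \log(RERI + e^{\beta_1} + e^{\beta_2} - 1) - \beta_1 - \beta_2}
#' so that the planted cell odds ratios realize the target RERI exactly.
#'
#' @param beta_prs,beta_ace Main-effect log odds ratios.
#' @param target_reri Desired RERI; must satisfy
#'   `target_reri + exp(beta_prs) + exp(beta_ace) - 1 > 0`.
#' @return The product-term log-OR coefficient (a single number).
#' @examples
#' plant_additive_interaction(log(2), log(1.5), 0.5)  # multiplicative null: 0
#' plant_additive_interaction(log(2), log(1.5), 0)    # additive null
#' @export
plant_additive_interaction <- function(beta_prs, beta_ace, target_reri) {
  stopifnot(is.numeric(beta_prs), is.numeric(beta_ace), is.numeric(target_reri))
  arg <- target_reri + exp(beta_prs) + exp(beta_ace) - 1
  if (any(arg <= 0))
    stop("infeasible target RERI: target_reri + exp(beta_prs) + exp(beta_ace) - 1 ",
         "must be positive", call. = FALSE)
  log(arg) - beta_prs - beta_ace
}

#' Assemble a full simulation scenario
#'
#' A scenario fixes everything about one synthetic cohort: its size, the
#' random seed, the threshold-score correlation structure per disorder, the
#' adversity-item endorsement rates, covariate distributions, and the planted
#' effect structure of every phenotype. Identical scenarios with identical
#' seeds reproduce identical cohorts bit for bit.
#'
#' @param n_participants Cohort size (>= 1).
#' @param seed Integer random seed.
#' @param prs_spec Named list with elements `scz` and `bip`, each a
#'   [prs_component_spec()].
#' @param ace_spec An [ace_spec()].
#' @param covariate_spec A [covariate_spec()].
#' @param outcomes Named list of [outcome_spec()]; names become cohort column
#'   names.
#' @return A list of class `psygxe_scenario`.
#' @export
simulation_scenario <- function(n_participants, seed = 1L,
                                prs_spec = list(scz = prs_component_spec(),
                                                bip = prs_component_spec()),
                                ace_spec = psygxe::ace_spec(),
                                covariate_spec = psygxe::covariate_spec(),
                                outcomes = list()) {
  n <- as.integer(n_participants)
  if (is.na(n) || n < 1L) stop_field("n_participants", "must be a positive integer")
  seed <- as.integer(seed)
  if (is.na(seed)) stop_field("seed", "must be an integer")
  if (!all(c("scz", "bip") %in% names(prs_spec)))
    stop_field("prs_spec", "must name components `scz` and `bip`")
  for (d in c("scz", "bip"))
    if (!inherits(prs_spec[[d]], "psygxe_prs_spec"))
      stop_field(paste0("prs_spec$", d), "must be built by prs_component_spec()")
  if (!inherits(ace_spec, "psygxe_ace_spec"))
    stop_field("ace_spec", "must be built by ace_spec()")
  if (!inherits(covariate_spec, "psygxe_covariate_spec"))
    stop_field("covariate_spec", "must be built by covariate_spec()")
  if (length(outcomes)) {
    if (is.null(names(outcomes)) || any(names(outcomes) == ""))
      stop_field("outcomes", "must be a named list")
    for (nm in names(outcomes))
      if (!inherits(outcomes[[nm]], "psygxe_outcome_spec"))
        stop_field(paste0("outcomes$", nm), "must be built by outcome_spec()")
  }
  structure(list(n_participants = n, seed = seed, prs_spec = prs_spec,
                 ace_spec = ace_spec, covariate_spec = covariate_spec,
                 outcomes = outcomes),
            class = "psygxe_scenario")
}
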