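# Scenario and cohort builders shared across tests.

# One-phenotype scenario with planted main and interaction effects.
interaction_scenario <- function(n, seed, prevalence = 0.3,
                                 beta_prs = log(1.5), beta_ace = log(1.5),
                                 scale = "multiplicative", value = 0,
                                 prs = "scz") {
  simulation_scenario(
    n, seed = seed,
    outcomes = list(sym = outcome_spec(
      prevalence = prevalence, prs = prs, beta_prs = beta_prs,
      beta_ace = beta_ace, interaction = list(scale = scale, value = value)))
  )
}

# Reconstruct the binary exposures the way the pipeline does, without
# needing a phenotype catalog.
add_exposures <- function(cohort) {
  cohort$any_ace <- derive_ace(cohort)$any_ace
  for (d in c("scz", "bip")) {
    cols <- grep(paste0("^", d, "_score_t"), names(cohort), value = TRUE)
    cohort[[paste0("prs_", d, "_high")]] <-
      dichotomize_prs(prs_pca(as.matrix(cohort[cols]))$score)
  }
  cohort
}

# Unadjusted interaction fit of the planted phenotype.
fit_gxe <- function(cohort, prs = "scz", covariates = character(),
                    outcome = "sym") {
  prs_col <- paste0("prs_", prs, "_high")
  fit_logistic(cohort, model_spec(
    outcome, c(prs_col, "any_ace"),
    interaction_terms = list(c(prs_col, "any_ace")),
    covariates = covariates))
}

gxe_terms <- function(prs = "scz") {
  prs_col <- paste0("prs_", prs, "_high")
  c(prs = prs_col, ace = "any_ace",
    interaction = paste0(prs_col, ":any_ace"))
}
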