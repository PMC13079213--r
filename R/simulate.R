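#' Generate a synthetic participant-level cohort
#'
#' Draws a cohort with the statistical structure the downstream models
#' assume: correlated per-threshold polygenic score columns for two
#' disorders, five ordinal adversity items with configurable endorsement
#' rates and inter-item correlation, covariates (sex, birth year, ordinal
#' socioeconomic covariates, deprivation index, genetic principal
#' components), and phenotype columns drawn from logistic models over the
#' dichotomized exposures (high PRS, any ACE) with planted main and
#' interaction effects.
#'
#' The exposures used to plant effects are exactly the ones the analysis
#' pipeline reconstructs: the PRS-PCA score of the threshold columns,
#' dichotomized at the 75th percentile, and the any-ACE flag derived from the
#' adversity items. Planted and estimated parameters therefore live on the
#' same scale.
#'
#' @param scenario A [simulation_scenario()].
#' @return A [tibble::tibble()] with `n_participants` rows: `participant_id`,
#'   covariates, `cts5_item_1 ... cts5_item_5` (ordinal codes 0--4, 0 =
#'   "Never true" ... 4 = "Very often true"), `scz_score_t1 ... t10`,
#'   `bip_score_t1 ... t10`, and one column per scenario outcome. A column
#'   dictionary is attached as attribute `"dictionary"`.
#' @examples
#' sc <- simulation_scenario(500, seed = 7,
#'   outcomes = list(sym_a = outcome_spec(prevalence = 0.3)))
#' cohort <- generate_cohort(sc)
#' mean(cohort$sym_a)
#' @export
generate_cohort <- function(scenario) {
  if (!inherits(scenario, "psygxe_scenario"))
    stop("`scenario` must be built by simulation_scenario()", call. = FALSE)
  n <- scenario$n_participants
  set.seed(scenario$seed)

  cov <- simulate_covariates(n, scenario$covariate_spec)
  scz <- simulate_threshold_scores(n, scenario$prs_spec$scz, "scz")
  bip <- simulate_threshold_scores(n, scenario$prs_spec$bip, "bip")
  cts <- simulate_cts_items(n, scenario$ace_spec)

  cohort <- tibble::as_tibble(c(list(participant_id = sprintf("P%07d", seq_len(n))),
                                cov, cts, as.list(scz), as.list(bip)))

  # exposures as the pipeline will reconstruct them
  ace_status <- derive_ace(cohort)
  ace <- ace_status$any_ace
  high <- list(
    scz = dichotomize_prs(prs_pca(as.matrix(scz))$score),
    bip = dichotomize_prs(prs_pca(as.matrix(bip))$score)
  )

  for (nm in names(scenario$outcomes)) {
    os <- scenario$outcomes[[nm]]
    h <- high[[os$prs]]
    ace_var <- switch(os$ace_term %||% "any",
                      any = ace,
                      count = ace_status$ace_count,
                      ace_status[[os$ace_term]])
    lp <- os$beta_prs * h + os$beta_ace * ace_var + os$beta_interaction * h * ace
    if (!is.null(os$covariate_betas)) {
      for (cn in names(os$covariate_betas)) {
        if (!cn %in% names(cohort))
          stop_field(paste0("covariate_betas[", cn, "]"), "no such cohort column")
        lp <- lp + os$covariate_betas[[cn]] * as.numeric(cohort[[cn]])
      }
    }
    cohort[[nm]] <- if (os$type == "binary") {
      rbinom(n, 1L, plogis(qlogis(os$prevalence) + lp))
    } else {
      rnorm(n) - lp  # planted risk lowers the continuous (cognition-like) score
    }
  }
  attr(cohort, "dictionary") <- cohort_dictionary(cohort, scenario)
  cohort
}

simulate_covariates <- function(n, cs) {
  out <- list(
    sex = factor(ifelse(runif(n) < cs$p_male, "male", "female"),
                 levels = c("female", "male")),
    birth_year = round(rnorm(n, cs$birth_year_mean, cs$birth_year_sd))
  )
  for (v in names(cs$n_levels)) {
    k <- cs$n_levels[[v]]
    out[[v]] <- factor(sample.int(k, n, replace = TRUE),
                       levels = seq_len(k),
                       labels = paste0("L", seq_len(k)))
  }
  out$imd <- exp(rnorm(n, log(15), 0.7))  # right-skewed deprivation index
  for (j in seq_len(cs$n_gpc)) out[[paste0("gpc", j)]] <- rnorm(n)
  out
}

simulate_threshold_scores <- function(n, ps, prefix) {
  m <- ps$n_thresholds
  rho <- ps$inter_threshold_correlation
  sigma <- matrix(rho, m, m); diag(sigma) <- 1
  z <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = sigma)
  scales <- 10^seq(-5, 0, length.out = m)  # raw scores differ by orders of magnitude
  z <- sweep(z, 2, scales, `*`)
  colnames(z) <- paste0(prefix, "_score_t", seq_len(m))
  as.data.frame(z)
}

# Ordinal category probabilities from the endorsement rate. Abuse items
# endorse at codes {2,3,4}; neglect items ("felt loved", "taken to doctor")
# endorse at codes {0,1}, so their mass is concentrated at the top codes.
cts_category_probs <- function(item, endorsement) {
  p <- endorsement
  if (item %in% c("emotional_neglect", "physical_neglect")) {
    c(0.4 * p, 0.6 * p, 0.2 * (1 - p), 0.3 * (1 - p), 0.5 * (1 - p))
  } else {
    c(0.75 * (1 - p), 0.25 * (1 - p), 0.60 * p, 0.25 * p, 0.15 * p)
  }
}

simulate_cts_items <- function(n, as) {
  items <- ace_item_names()
  sigma <- matrix(as$item_correlation, 5, 5); diag(sigma) <- 1
  u <- pnorm(MASS::mvrnorm(n, mu = rep(0, 5), Sigma = sigma))
  out <- list()
  for (j in seq_along(items)) {
    cuts <- cumsum(cts_category_probs(items[j], as$endorsement[[items[j]]]))
    out[[paste0("cts5_item_", j)]] <- findInterval(u[, j], cuts[-5])
  }
  if (as$missing_rate > 0) {
    miss <- matrix(runif(5L * n) < as$missing_rate, n, 5)
    # inclusion rule: every retained participant keeps >= 1 observed item
    all_gone <- rowSums(miss) == 5L
    if (any(all_gone))
      miss[cbind(which(all_gone), sample.int(5, sum(all_gone), replace = TRUE))] <- FALSE
    for (j in 1:5) out[[j]][miss[, j]] <- NA_integer_
  }
  out
}

cohort_dictionary <- function(cohort, scenario) {
  role <- function(col) {
    if (col == "participant_id") return(list(role = "id"))
    if (grepl("^cts5_item_", col))
      return(list(role = "adversity_item",
                  levels = c("0=Never true", "1=Rarely true", "2=Sometimes true",
                             "3=Often", "4=Very often true"),
                  item = ace_item_names()[as.integer(sub("^cts5_item_", "", col))]))
    if (grepl("^(scz|bip)_score_t", col)) return(list(role = "threshold_score"))
    if (grepl("^gpc", col)) return(list(role = "covariate", type = "genetic_pc"))
    if (col %in% c("sex", "birth_year", "employment", "income", "smoking",
                   "education", "imd"))
      return(c(list(role = "covariate"),
               if (is.factor(cohort[[col]])) list(levels = levels(cohort[[col]]))))
    os <- scenario$outcomes[[col]]
    if (!is.null(os)) return(list(role = "symptom_item", type = os$type))
    list(role = "other")
  }
  setNames(lapply(names(cohort), role), names(cohort))
}

#' Write a cohort to disk as TSV plus a JSON data dictionary
#'
#' @param cohort A cohort table from [generate_cohort()] (or compatible).
#' @param path Output TSV path.
#' @param dictionary_path Output JSON path; defaults to `path` with a
#'   `.dictionary.json` suffix.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, path,
                         dictionary_path = sub("\\.tsv$", "", path)) {
  if (!grepl("\\.json$", dictionary_path))
    dictionary_path <- paste0(dictionary_path, ".dictionary.json")
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dict <- attr(cohort, "dictionary")
  if (is.null(dict)) dict <- cohort_dictionary(cohort, list(outcomes = list()))
  jsonlite::write_json(dict, dictionary_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, dictionary_path))
}

#' Read a cohort TSV written by [write_cohort()]
#'
#' Factor levels for categorical covariates are restored from the data
#' dictionary when present.
#'
#' @param path Cohort TSV path.
#' @param dictionary_path Optional dictionary JSON path; auto-detected from
#'   `path` when present on disk.
#' @return A tibble.
#' @export
read_cohort <- function(path,
                        dictionary_path = paste0(sub("\\.tsv$", "", path),
                                                 ".dictionary.json")) {
  cohort <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                                stringsAsFactors = FALSE))
  if (file.exists(dictionary_path)) {
    dict <- jsonlite::read_json(dictionary_path)
    for (col in names(dict)) {
      lv <- unlist(dict[[col]]$levels)
      if (!is.null(lv) && col %in% names(cohort) && !grepl("^cts5", col))
        cohort[[col]] <- factor(cohort[[col]], levels = lv)
    }
    attr(cohort, "dictionary") <- dict
  }
  cohort
}
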