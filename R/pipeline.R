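#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 61 * 3)  # 2.73e-4, the screening tier
#' bonferroni_alpha(0.05, 26)      # 1.92e-3, an interaction tier
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  check_prob(alpha, "alpha")
  n_tests <- as.integer(n_tests)
  if (is.na(n_tests) || n_tests < 1L)
    stop_field("n_tests", "must be an integer >= 1")
  alpha / n_tests
}

#' Pipeline configuration
#'
#' @param covariates Adjustment columns for every model; default
#'   [default_covariates()].
#' @param alpha Family-wise significance level (default 0.05).
#' @param exposures Named character vector mapping the three canonical
#'   exposures (`ace`, `prs_scz`, `prs_bip`) to cohort columns.
#' @param sensitivity List of toggles: `covariate_products` (Keller-style
#'   covariate x exposure adjustment), `dose_response` (ACE count 0--5),
#'   `ace_types` (five per-type exposures), `row_filter` (optional logical
#'   column name; rows where it is TRUE are kept, e.g. an ancestry subset).
#' @param dose_coding `"linear"` (per additional ACE) or `"categorical"`.
#' @param seed Integer seed recorded in the run manifest.
#' @return A list of class `psygxe_config`.
#' @export
pipeline_config <- function(covariates = default_covariates(),
                            alpha = 0.05,
                            exposures = c(ace = "any_ace",
                                          prs_scz = "prs_scz_high",
                                          prs_bip = "prs_bip_high"),
                            sensitivity = list(covariate_products = TRUE,
                                               dose_response = TRUE,
                                               ace_types = TRUE,
                                               row_filter = NULL),
                            dose_coding = c("linear", "categorical"),
                            seed = 1L) {
  check_prob(alpha, "alpha")
  if (!all(c("ace", "prs_scz", "prs_bip") %in% names(exposures)))
    stop_field("exposures", "must map `ace`, `prs_scz` and `prs_bip`")
  structure(list(covariates = covariates, alpha = alpha,
                 exposures = exposures, sensitivity = sensitivity,
                 dose_coding = match.arg(dose_coding),
                 seed = as.integer(seed)),
            class = "psygxe_config")
}

#' Attach derived exposures and phenotypes to a raw cohort
#'
#' Runs the full derivation stage: ACE status and every catalog phenotype
#' ([derive_phenotypes()]), then per-disorder PRS aggregation
#' ([prs_pca()] on the ten threshold-score columns, standardized once over
#' all rows with complete scores) and top-quartile dichotomization. Adds
#' `prs_scz_score`, `prs_scz_high`, `prs_bip_score`, `prs_bip_high`.
#'
#' @param cohort Raw cohort table (items + threshold scores + covariates).
#' @param catalog A [phenotype_catalog()].
#' @return The augmented cohort.
#' @export
prepare_cohort <- function(cohort, catalog) {
  cohort <- derive_phenotypes(cohort, catalog)
  for (d in c("scz", "bip")) {
    cols <- grep(paste0("^", d, "_score_t"), names(cohort), value = TRUE)
    if (length(cols) < 2L)
      stop("cohort lacks per-threshold score columns `", d, "_score_t*`",
           call. = FALSE)
    m <- as.matrix(cohort[cols])
    ok <- complete.cases(m)
    score <- rep(NA_real_, nrow(cohort))
    high <- rep(NA_integer_, nrow(cohort))
    res <- prs_pca(m[ok, , drop = FALSE])
    score[ok] <- res$score
    high[ok] <- res$high
    cohort[[paste0("prs_", d, "_score")]] <- score
    cohort[[paste0("prs_", d, "_high")]] <- high
  }
  cohort
}

# Run one model, returning either a tidy row set or an exclusion record.
# Every attempted model lands in exactly one of the two.
attempt_fit <- function(cohort, spec, stage, phenotype, exposure_key) {
  out <- tryCatch({
    fit <- fit_logistic(cohort, spec)
    if (fit$separation_flag)
      list(fit = NULL, reason = "flagged: quasi-complete separation or non-convergence")
    else list(fit = fit, reason = NA_character_)
  }, error = function(e) list(fit = NULL, reason = conditionMessage(e)))
  out$log <- tibble::tibble(stage = stage, phenotype = phenotype,
                            exposure = exposure_key,
                            status = if (is.null(out$fit)) "excluded" else "fitted",
                            reason = out$reason)
  out
}

phen_column <- function(id) paste0("phen_", id)

#' Univariate screening of every phenotype against every exposure
#'
#' Fits one covariate-adjusted logistic model per phenotype x exposure
#' (ACE, PRS for each disorder) and applies a Bonferroni tier of
#' `alpha / (n_phenotypes x n_exposures)` computed from the realized
#' catalog. A phenotype is selected for the downstream joint and interaction
#' stages of a given PRS only when both that PRS and ACE pass the corrected
#' tier on it.
#'
#' @param cohort A prepared cohort (see [prepare_cohort()]).
#' @param catalog A [phenotype_catalog()].
#' @param config A [pipeline_config()].
#' @return A list of class `psygxe_screen`: `results` (one row per fitted
#'   phenotype x exposure: OR, CI, p, n, `pass_univariate`), `selection`
#'   (one row per phenotype x PRS with `selected_for_joint`),
#'   `alpha_univariate`, `n_tests`, and `log` (every attempted model with
#'   its status).
#' @export
run_univariate_screen <- function(cohort, catalog, config) {
  exposures <- config$exposures
  n_tests <- nrow(catalog) * length(exposures)
  alpha_uni <- bonferroni_alpha(config$alpha, n_tests)
  rows <- list(); logs <- list()
  for (i in seq_len(nrow(catalog))) {
    pid <- catalog$phenotype_id[i]
    for (key in names(exposures)) {
      spec <- model_spec(phen_column(pid), exposures[[key]],
                         covariates = config$covariates)
      att <- attempt_fit(cohort, spec, "univariate", pid, key)
      logs[[length(logs) + 1L]] <- att$log
      if (is.null(att$fit)) next
      td <- tidy_fit(att$fit)
      td <- td[td$term == exposures[[key]], ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        phenotype = pid, domain = catalog$domain[i], level = catalog$level[i],
        exposure = key, or = td$or, ci_low = td$ci_low, ci_high = td$ci_high,
        beta = td$beta, se = td$se, p = td$p, n = td$n,
        pass_univariate = td$p < alpha_uni)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(phenotype = character(), domain = character(),
                   level = character(), exposure = character(), or = double(),
                   ci_low = double(), ci_high = double(), beta = double(),
                   se = double(), p = double(), n = integer(),
                   pass_univariate = logical())
  sel_rows <- list()
  for (prs in c("prs_scz", "prs_bip")) {
    for (pid in catalog$phenotype_id) {
      pass <- function(key) {
        r <- results[results$phenotype == pid & results$exposure == key, ]
        nrow(r) == 1L && isTRUE(r$pass_univariate)
      }
      sel_rows[[length(sel_rows) + 1L]] <- tibble::tibble(
        phenotype = pid, prs = prs,
        selected_for_joint = pass(prs) && pass("ace"))
    }
  }
  structure(list(results = results, selection = do.call(rbind, sel_rows),
                 alpha_univariate = alpha_uni, n_tests = n_tests,
                 log = do.call(rbind, logs)),
            class = "psygxe_screen")
}

selected_pairs <- function(screen) {
  sel <- screen$selection
  sel[sel$selected_for_joint, c("phenotype", "prs")]
}

#' Joint main-effect models for the selected phenotypes
#'
#' For every phenotype selected for a PRS, fits the joint model with both
#' that PRS and ACE as exposures (covariate-adjusted), and reports each
#' adjusted OR next to its univariate counterpart so attenuation after
#' adjusting for the partner exposure is directly visible.
#'
#' @param cohort Prepared cohort.
#' @param screen A `psygxe_screen` from [run_univariate_screen()].
#' @param config A [pipeline_config()].
#' @return A list with `results` (one row per selected phenotype x PRS x
#'   exposure: joint OR/CI/p plus univariate OR) and `log`. Empty selection
#'   yields empty tables.
#' @export
run_joint_models <- function(cohort, screen, config) {
  pairs <- selected_pairs(screen)
  rows <- list(); logs <- list()
  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$phenotype[i]; prs <- pairs$prs[i]
    cols <- config$exposures[c(prs, "ace")]
    spec <- model_spec(phen_column(pid), unname(cols),
                       covariates = config$covariates)
    att <- attempt_fit(cohort, spec, "joint", pid, prs)
    logs[[length(logs) + 1L]] <- att$log
    if (is.null(att$fit)) next
    td <- tidy_fit(att$fit)
    for (key in names(cols)) {
      tr <- td[td$term == cols[[key]], ]
      uni <- screen$results[screen$results$phenotype == pid &
                              screen$results$exposure == key, ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        phenotype = pid, prs_family = prs, exposure = key,
        or = tr$or, ci_low = tr$ci_low, ci_high = tr$ci_high, p = tr$p,
        n = tr$n,
        or_univariate = if (nrow(uni) == 1L) uni$or else NA_real_)
    }
  }
  empty <- tibble::tibble(phenotype = character(), prs_family = character(),
                          exposure = character(), or = double(),
                          ci_low = double(), ci_high = double(), p = double(),
                          n = integer(), or_univariate = double())
  list(results = if (length(rows)) do.call(rbind, rows) else empty,
       log = if (length(logs)) do.call(rbind, logs) else
         tibble::tibble(stage = character(), phenotype = character(),
                        exposure = character(), status = character(),
                        reason = character()))
}

interaction_fit_spec <- function(pid, prs, config,
                                 covariate_products = FALSE) {
  cols <- config$exposures[c(prs, "ace")]
  prods <- if (covariate_products) {
    unlist(lapply(config$covariates,
                  function(cv) lapply(unname(cols), function(e) c(cv, e))),
           recursive = FALSE)
  } else list()
  model_spec(phen_column(pid), unname(cols),
             interaction_terms = list(unname(cols)),
             covariates = config$covariates,
             extra_product_terms = prods)
}

#' Additive and multiplicative interaction models for the selected phenotypes
#'
#' For every selected phenotype x PRS, fits the interaction model (both main
#' effects plus their product, covariate-adjusted) and derives the RERI with
#' delta-method CI ([reri_from_fit()]) and the multiplicative product-term
#' coefficient ([multiplicative_from_fit()]). Two significance tiers are
#' applied: nominal (`alpha`) and per-PRS Bonferroni, whose denominator is
#' the realized number of phenotypes selected for that PRS.
#'
#' @param cohort Prepared cohort.
#' @param screen A `psygxe_screen`.
#' @param config A [pipeline_config()].
#' @param covariate_products If `TRUE`, every fit additionally adjusts for
#'   all covariate x PRS and covariate x ACE product terms (used by the
#'   sensitivity stage).
#' @param stage Stage label recorded in the model log.
#' @return A list with `additive` (RERI table, including the excess-risk
#'   decomposition), `multiplicative`, `alpha_interaction` (per-PRS tiers),
#'   and `log`.
#' @export
run_interaction_models <- function(cohort, screen, config,
                                   covariate_products = FALSE,
                                   stage = "interaction") {
  pairs <- selected_pairs(screen)
  n_sel <- table(factor(pairs$prs, levels = c("prs_scz", "prs_bip")))
  tiers <- vapply(c(prs_scz = "prs_scz", prs_bip = "prs_bip"), function(p) {
    if (n_sel[[p]] >= 1L) bonferroni_alpha(config$alpha, n_sel[[p]]) else NA_real_
  }, 0)
  add_rows <- list(); mul_rows <- list(); logs <- list()
  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$phenotype[i]; prs <- pairs$prs[i]
    cols <- config$exposures[c(prs, "ace")]
    int_term <- paste(cols, collapse = ":")
    spec <- interaction_fit_spec(pid, prs, config, covariate_products)
    att <- attempt_fit(cohort, spec, stage, pid, prs)
    logs[[length(logs) + 1L]] <- att$log
    if (is.null(att$fit)) next
    add <- reri_from_fit(att$fit, cols[[1]], cols[[2]], int_term)
    mul <- multiplicative_from_fit(att$fit, int_term)
    tier <- tiers[[prs]]
    add_rows[[length(add_rows) + 1L]] <- tibble::tibble(
      phenotype = pid, prs_family = prs,
      reri = add$reri, se = add$se, ci_low = add$ci95[1], ci_high = add$ci95[2],
      p = add$p, or_11 = add$or_11, or_10 = add$or_10, or_01 = add$or_01,
      excess_prs = add$excess_prs, excess_ace = add$excess_ace,
      classification = classify_additive(add), n = att$fit$n_used,
      alpha_bonferroni = tier,
      pass_nominal = add$p < config$alpha,
      pass_bonferroni = add$p < tier)
    mul_rows[[length(mul_rows) + 1L]] <- tibble::tibble(
      phenotype = pid, prs_family = prs,
      coefficient = mul$coefficient, se = mul$se, p = mul$p,
      direction = mul$direction, n = att$fit$n_used,
      alpha_bonferroni = tier,
      pass_nominal = mul$p < config$alpha,
      pass_bonferroni = mul$p < tier)
  }
  empty_add <- tibble::tibble(phenotype = character(), prs_family = character(),
                              reri = double(), se = double(), ci_low = double(),
                              ci_high = double(), p = double(), or_11 = double(),
                              or_10 = double(), or_01 = double(),
                              excess_prs = double(), excess_ace = double(),
                              classification = character(), n = integer(),
                              alpha_bonferroni = double(),
                              pass_nominal = logical(), pass_bonferroni = logical())
  empty_mul <- tibble::tibble(phenotype = character(), prs_family = character(),
                              coefficient = double(), se = double(), p = double(),
                              direction = character(), n = integer(),
                              alpha_bonferroni = double(),
                              pass_nominal = logical(), pass_bonferroni = logical())
  list(additive = if (length(add_rows)) do.call(rbind, add_rows) else empty_add,
       multiplicative = if (length(mul_rows)) do.call(rbind, mul_rows) else empty_mul,
       alpha_interaction = tiers,
       log = if (length(logs)) do.call(rbind, logs) else
         tibble::tibble(stage = character(), phenotype = character(),
                        exposure = character(), status = character(),
                        reason = character()))
}

#' Sensitivity analyses
#'
#' Three optional re-analyses, mirroring common robustness checks for
#' gene-environment interaction studies:
#' \describe{
#'   \item{covariate products}{re-fits every interaction model after adding
#'     all covariate x PRS and covariate x ACE product terms, so covariate
#'     confounding cannot masquerade as gene-environment interaction.}
#'   \item{dose response}{models with the ACE count (0--5) as the adversity
#'     exposure on the domain-level phenotypes, univariate and joint with
#'     each PRS; linear coding by default, categorical optional.}
#'   \item{ACE types}{models with the five per-type flags (physical,
#'     emotional, sexual abuse; emotional, physical neglect) as exposures on
#'     the domain-level phenotypes, each type alone and all five jointly.}
#' }
#' A row filter (e.g. an ancestry subset flag) may restrict all of them.
#'
#' @param cohort Prepared cohort.
#' @param screen A `psygxe_screen`.
#' @param config A [pipeline_config()]; toggles in `config$sensitivity`
#'   choose which blocks run.
#' @param catalog The catalog (needed for the domain-level phenotype list).
#' @return A list with elements `covariate_products` (interaction tables as
#'   in [run_interaction_models()]), `dose_response`, `ace_types`, and `log`.
#' @export
run_sensitivity <- function(cohort, screen, config, catalog) {
  toggles <- config$sensitivity
  filt <- toggles$row_filter
  if (!is.null(filt)) {
    if (!filt %in% names(cohort))
      stop_field("sensitivity$row_filter", "column not found in cohort")
    cohort <- cohort[which(cohort[[filt]] %in% c(TRUE, 1L)), , drop = FALSE]
  }
  out <- list(covariate_products = NULL, dose_response = NULL,
              ace_types = NULL)
  logs <- list()

  if (isTRUE(toggles$covariate_products)) {
    ext <- run_interaction_models(cohort, screen, config,
                                  covariate_products = TRUE,
                                  stage = "sensitivity_covariate_products")
    out$covariate_products <- ext[c("additive", "multiplicative")]
    logs[[length(logs) + 1L]] <- ext$log
  }

  domains <- catalog$phenotype_id[catalog$level %in% c("domain", "both")]
  if (isTRUE(toggles$dose_response)) {
    cohort$ace_count_term <- if (config$dose_coding == "categorical")
      factor(cohort$ace_count) else cohort$ace_count  # observed levels only
    rows <- list()
    for (pid in domains) {
      for (prs in c(NA_character_, "prs_scz", "prs_bip")) {
        exps <- c("ace_count_term",
                  if (!is.na(prs)) unname(config$exposures[[prs]]))
        spec <- model_spec(phen_column(pid), exps, covariates = config$covariates)
        att <- attempt_fit(cohort, spec, "sensitivity_dose_response", pid,
                           if (is.na(prs)) "ace_count" else paste0("ace_count+", prs))
        logs[[length(logs) + 1L]] <- att$log
        if (is.null(att$fit)) next
        td <- tidy_fit(att$fit)
        tr <- td[grepl("^ace_count_term", td$term), ]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          phenotype = pid,
          model = if (is.na(prs)) "univariate" else paste0("joint_", prs),
          term = tr$term, or = tr$or, ci_low = tr$ci_low,
          ci_high = tr$ci_high, p = tr$p, n = tr$n)
      }
    }
    out$dose_response <- if (length(rows)) do.call(rbind, rows) else
      tibble::tibble(phenotype = character(), model = character(),
                     term = character(), or = double(), ci_low = double(),
                     ci_high = double(), p = double(), n = integer())
  }

  if (isTRUE(toggles$ace_types)) {
    types <- ace_item_names()
    rows <- list()
    for (pid in domains) {
      for (ty in types) {
        spec <- model_spec(phen_column(pid), ty, covariates = config$covariates)
        att <- attempt_fit(cohort, spec, "sensitivity_ace_types", pid, ty)
        logs[[length(logs) + 1L]] <- att$log
        if (is.null(att$fit)) next
        td <- tidy_fit(att$fit); tr <- td[td$term == ty, ]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          phenotype = pid, model = "univariate", ace_type = ty,
          or = tr$or, ci_low = tr$ci_low, ci_high = tr$ci_high,
          p = tr$p, n = tr$n)
      }
      spec <- model_spec(phen_column(pid), types, covariates = config$covariates)
      att <- attempt_fit(cohort, spec, "sensitivity_ace_types", pid, "all_types")
      logs[[length(logs) + 1L]] <- att$log
      if (!is.null(att$fit)) {
        td <- tidy_fit(att$fit); tr <- td[td$term %in% types, ]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          phenotype = pid, model = "joint", ace_type = tr$term,
          or = tr$or, ci_low = tr$ci_low, ci_high = tr$ci_high,
          p = tr$p, n = tr$n)
      }
    }
    out$ace_types <- if (length(rows)) do.call(rbind, rows) else
      tibble::tibble(phenotype = character(), model = character(),
                     ace_type = character(), or = double(), ci_low = double(),
                     ci_high = double(), p = double(), n = integer())
  }
  out$log <- if (length(logs)) do.call(rbind, logs) else
    tibble::tibble(stage = character(), phenotype = character(),
                   exposure = character(), status = character(),
                   reason = character())
  out
}

#' Run the whole screening cascade and write its report tables
#'
#' Orchestrates derivation, univariate screening, joint models, interaction
#' models and (optionally) sensitivity analyses, then writes tidy TSVs, an
#' exclusion log and a JSON run manifest to `output_dir`. With a fixed
#' cohort and configuration the outputs are byte-identical across runs.
#'
#' @param cohort Raw cohort table (as generated by [generate_cohort()] or
#'   read from disk).
#' @param catalog A [phenotype_catalog()].
#' @param config A [pipeline_config()].
#' @param output_dir Output directory, created if needed; `NULL` skips
#'   writing.
#' @return A list with `screen`, `joint`, `interaction`, `sensitivity`,
#'   `log` (all attempted models), and `paths` of the written files.
#' @export
run_pipeline <- function(cohort, catalog, config, output_dir = NULL) {
  cohort <- prepare_cohort(cohort, catalog)
  screen <- run_univariate_screen(cohort, catalog, config)
  joint <- run_joint_models(cohort, screen, config)
  inter <- run_interaction_models(cohort, screen, config)
  sens <- if (any(unlist(config$sensitivity[c("covariate_products",
                                              "dose_response", "ace_types")])))
    run_sensitivity(cohort, screen, config, catalog) else NULL
  log <- do.call(rbind, c(list(screen$log, joint$log, inter$log),
                          if (!is.null(sens)) list(sens$log)))
  paths <- character()
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(tab, name) {
      p <- file.path(output_dir, paste0(name, ".tsv"))
      utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    paths <- c(
      wt(screen$results, "univariate_screen"),
      wt(screen$selection, "selection"),
      wt(joint$results, "joint_models"),
      wt(inter$additive, "interaction_additive"),
      wt(inter$multiplicative, "interaction_multiplicative"),
      wt(inter$additive[, c("phenotype", "prs_family", "excess_prs",
                            "excess_ace", "reri", "ci_low", "ci_high")],
         "excess_risk_decomposition"),
      if (!is.null(sens$covariate_products))
        wt(sens$covariate_products$multiplicative,
           "sensitivity_covariate_products"),
      if (!is.null(sens$dose_response))
        wt(sens$dose_response, "sensitivity_dose_response"),
      if (!is.null(sens$ace_types)) wt(sens$ace_types, "sensitivity_ace_types"),
      wt(log, "model_log"))
    manifest <- list(
      package = "psygxe",
      package_version = as.character(utils::packageVersion("psygxe")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      alpha = config$alpha,
      n_phenotypes = nrow(catalog),
      n_participants = nrow(cohort),
      alpha_univariate = screen$alpha_univariate,
      alpha_interaction = as.list(inter$alpha_interaction),
      n_selected = as.list(table(selected_pairs(screen)$prs)))
    mp <- file.path(output_dir, "run_manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths <- c(paths, mp)
  }
  list(screen = screen, joint = joint, interaction = inter,
       sensitivity = sens, log = log, paths = paths)
}
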