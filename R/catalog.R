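#' Build a phenotype catalog
#'
#' A catalog lists every distinct binary phenotype the screening cascade
#' analyses: symptom-level entries (each constructed from one cohort item
#' column by a registered rule) and domain-level entries (endorsed when any
#' member symptom is endorsed). A domain containing a single symptom is one
#' phenotype, not two: its entry carries level `"both"`.
#'
#' @param entries A data frame with columns `phenotype_id`, `label`, `domain`,
#'   `level` (`"symptom"`, `"domain"` or `"both"`), `rule` (`"direct"`,
#'   `"ordinal_ge"` or `"quantile"` for symptom construction; `NA` for domain
#'   entries), `rule_param` (numeric or `NA`) and a list column `members`
#'   (item column names for symptoms; member symptom `phenotype_id`s for
#'   domains).
#' @return The validated catalog (a tibble of class `psygxe_catalog`).
#' @export
phenotype_catalog <- function(entries) {
  entries <- tibble::as_tibble(entries)
  need <- c("phenotype_id", "label", "domain", "level", "rule", "rule_param", "members")
  if (!all(need %in% names(entries)))
    stop_field("entries", paste("must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(entries$phenotype_id))
    stop_field("phenotype_id", "must be unique")
  if (!all(entries$level %in% c("symptom", "domain", "both")))
    stop_field("level", "must be \"symptom\", \"domain\" or \"both\"")
  sym <- entries$level %in% c("symptom", "both")
  if (!all(entries$rule[sym] %in% c("direct", "ordinal_ge", "quantile")))
    stop("configuration error: unregistered symptom construction rule; ",
         "registered rules are \"direct\", \"ordinal_ge\", \"quantile\"",
         call. = FALSE)
  dom <- entries$level %in% c("domain", "both")
  for (i in which(dom)) {
    mem <- entries$members[[i]]
    if (length(mem) < 1L)
      stop_field("members", paste0("domain entry `", entries$phenotype_id[i],
                                   "` needs at least one member symptom"))
    if (entries$level[i] == "domain") {
      known <- entries$phenotype_id[sym]
      if (!all(mem %in% known))
        stop_field("members", paste0("domain `", entries$phenotype_id[i],
                                     "` references unknown symptoms: ",
                                     paste(setdiff(mem, known), collapse = ", ")))
    }
  }
  class(entries) <- c("psygxe_catalog", class(entries))
  entries
}

#' Summary counts of a catalog
#'
#' @param catalog A [phenotype_catalog()].
#' @return A list with `n_symptoms` (symptom-level entries), `n_domains`,
#'   and `n_phenotypes` (distinct phenotypes; a single-symptom domain counts
#'   once).
#' @export
catalog_counts <- function(catalog) {
  list(n_symptoms = sum(catalog$level %in% c("symptom", "both")),
       n_domains = length(unique(catalog$domain[catalog$level %in% c("domain", "both")])),
       n_phenotypes = nrow(catalog))
}

#' Construct a catalog from domain sizes
#'
#' Generic builder used both for the default 7-domain catalog and for reduced
#' synthetic catalogs in simulation studies. Each non-cognition domain gets
#' `domain_sizes[d]` direct-binary symptoms named `<domain>_s<j>` over item
#' columns of the same name; the cognition domain gets continuous test-score
#' items dichotomized at an impairment quantile (low score = impaired).
#' Single-symptom domains collapse to one phenotype entry of level `"both"`.
#'
#' @param domain_sizes Named integer vector: symptoms per domain.
#' @param cognition_domain Name of the domain treated as continuous test
#'   scores, or `NA` for none.
#' @param impairment_quantile Quantile below which a continuous test score is
#'   counted as impaired. Default lowest quartile.
#' @return A [phenotype_catalog()].
#' @export
build_catalog <- function(domain_sizes, cognition_domain = NA_character_,
                          impairment_quantile = 0.25) {
  check_prob(impairment_quantile, "impairment_quantile")
  rows <- list()
  for (d in names(domain_sizes)) {
    k <- domain_sizes[[d]]
    is_cog <- identical(d, cognition_domain)
    ids <- paste0(d, "_s", seq_len(k))
    single <- k == 1L
    for (j in seq_len(k)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        phenotype_id = ids[j],
        label = paste0(gsub("_", " ", d), " symptom ", j),
        domain = d,
        level = if (single) "both" else "symptom",
        rule = if (is_cog) "quantile" else "direct",
        rule_param = if (is_cog) impairment_quantile else NA_real_,
        members = list(ids[j])
      )
    }
    if (!single) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        phenotype_id = paste0("dom_", d),
        label = paste0(gsub("_", " ", d), " domain"),
        domain = d, level = "domain",
        rule = NA_character_, rule_param = NA_real_,
        members = list(ids)
      )
    }
  }
  phenotype_catalog(do.call(rbind, rows))
}

#' The default seven-domain phenotype catalog
#'
#' Fifty-five symptom-level phenotypes across seven domains — psychotic,
#' mania, depression, anxiety, help-seeking, self-harm/suicide, and cognition
#' — plus domain-level endorsement phenotypes. Help-seeking consists of a
#' single symptom, so its symptom and domain are the same phenotype and the
#' catalog lists 61 distinct phenotypes. The three cognition phenotypes are
#' continuous test scores (numeric memory, fluid intelligence, prospective
#' memory) dichotomized at the lowest quartile. The per-domain symptom split
#' outside cognition and help-seeking is a structural stand-in: the screening
#' machinery only needs the counts, domain membership and construction rules.
#'
#' @param impairment_quantile Impairment cut for cognition scores.
#' @return A [phenotype_catalog()] with 61 entries.
#' @export
default_phenotype_catalog <- function(impairment_quantile = 0.25) {
  build_catalog(
    c(psychotic = 7L, mania = 6L, depression = 14L, anxiety = 16L,
      help_seeking = 1L, self_harm = 8L, cognition = 3L),
    cognition_domain = "cognition",
    impairment_quantile = impairment_quantile
  )
}

#' Read / write a catalog as JSON
#'
#' @param path JSON file path.
#' @param catalog A [phenotype_catalog()].
#' @return `read_catalog()` returns a validated catalog; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  raw <- jsonlite::read_json(path)
  entries <- tibble::tibble(
    phenotype_id = vapply(raw, `[[`, "", "phenotype_id"),
    label = vapply(raw, `[[`, "", "label"),
    domain = vapply(raw, `[[`, "", "domain"),
    level = vapply(raw, `[[`, "", "level"),
    rule = vapply(raw, function(e) e$rule %||% NA_character_, ""),
    rule_param = vapply(raw, function(e) as.numeric(e$rule_param %||% NA_real_), 0),
    members = lapply(raw, function(e) unlist(e$members))
  )
  phenotype_catalog(entries)
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    e <- as.list(catalog[i, setdiff(names(catalog), "members")])
    e$members <- catalog$members[[i]]
    e
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
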