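#' Derive adversity status from the five CTS-5 items
#'
#' The three abuse items (physically abused by family, felt hated by a family
#' member, sexually molested) are endorsed when the response is "Sometimes
#' true", "Often" or "Very often true" (codes 2--4). The two neglect items
#' (felt loved as a child, someone to take to doctor when needed) are reverse
#' scored: they are endorsed when the response is "Never true" or "Rarely
#' true" (codes 0--1). Any-ACE is positive when at least one observed item is
#' endorsed; the ACE count sums the endorsed items. Codes outside 0--4 (e.g.
#' "prefer not to answer" sentinels) are treated as missing.
#'
#' Participants with some missing items are classified from the observed
#' items only: `any_ace = 0` requires every *observed* item to be
#' non-endorsed. Participants with all five items missing cannot be
#' classified; their rows get `NA` throughout and are listed in the
#' `"exclusions"` attribute of the result, mirroring the inclusion rule that
#' requires information on at least one adversity item.
#'
#' @param cohort A data frame containing the five item columns.
#' @param items Character vector of the five item column names, in the order
#'   physical abuse, emotional abuse, sexual abuse, emotional neglect,
#'   physical neglect.
#' @return A tibble with one row per cohort row: `any_ace`, `ace_count`, and
#'   the five type flags (`physical_abuse`, ..., `physical_neglect`), each
#'   possibly `NA`. Attribute `"exclusions"` is a tibble of excluded rows
#'   (row index, participant id when available, reason).
#' @examples
#' x <- data.frame(cts5_item_1 = c(2, 0), cts5_item_2 = c(0, 0),
#'                 cts5_item_3 = c(0, 0), cts5_item_4 = c(4, 4),
#'                 cts5_item_5 = c(3, 2))
#' derive_ace(x)  # row 1: physical abuse endorsed; row 2: nothing endorsed
#' @export
derive_ace <- function(cohort, items = paste0("cts5_item_", 1:5)) {
  if (length(items) != 5L || !all(items %in% names(cohort)))
    stop_field("items", "must name five columns present in `cohort`")
  resp <- lapply(items, function(cl) {
    x <- as.numeric(cohort[[cl]])
    x[!is.na(x) & !(x %in% 0:4)] <- NA_real_  # out-of-range codes -> missing
    x
  })
  flags <- vector("list", 5L)
  for (j in 1:3) flags[[j]] <- as.integer(resp[[j]] >= 2)
  for (j in 4:5) flags[[j]] <- as.integer(resp[[j]] <= 1)
  fm <- do.call(cbind, flags)
  n_obs <- rowSums(!is.na(fm))
  any_ace <- as.integer(rowSums(fm == 1L, na.rm = TRUE) > 0)
  any_ace[n_obs == 0L] <- NA_integer_
  ace_count <- as.integer(rowSums(fm, na.rm = TRUE))
  ace_count[n_obs == 0L] <- NA_integer_
  out <- tibble::tibble(any_ace = any_ace, ace_count = ace_count)
  for (j in 1:5) out[[ace_item_names()[j]]] <- fm[, j]
  excluded <- which(n_obs == 0L)
  attr(out, "exclusions") <- tibble::tibble(
    row = excluded,
    participant_id = if ("participant_id" %in% names(cohort))
      cohort$participant_id[excluded] else NA_character_,
    reason = rep("all five CTS-5 items missing", length(excluded))
  )
  out
}

#' Derive one binary symptom from an item column
#'
#' Construction rules, registered in the phenotype catalog:
#' \describe{
#'   \item{`direct`}{the item is already binary (0/1, logical, or
#'     "yes"/"no"); passed through.}
#'   \item{`ordinal_ge`}{endorsed when the ordinal code is at or above
#'     `param`.}
#'   \item{`quantile`}{for continuous test scores: impaired (= 1) when the
#'     score is below the `param` quantile of the observed scores.}
#' }
#' Missing values propagate; models downstream are complete-case.
#'
#' @param x The item column.
#' @param rule One of `"direct"`, `"ordinal_ge"`, `"quantile"`.
#' @param param Rule parameter (cut code or quantile).
#' @return Integer vector of 0/1/`NA`.
#' @export
derive_symptom <- function(x, rule, param = NA_real_) {
  switch(rule,
    direct = {
      if (is.character(x) || is.factor(x)) {
        as.integer(tolower(as.character(x)) == "yes")
      } else {
        y <- as.integer(x)
        if (any(!(y[!is.na(y)] %in% c(0L, 1L))))
          stop("configuration error: `direct` rule applied to a non-binary item",
               call. = FALSE)
        y
      }
    },
    ordinal_ge = as.integer(as.numeric(x) >= param),
    quantile = {
      cut <- quantile(as.numeric(x), param, na.rm = TRUE, names = FALSE)
      as.integer(as.numeric(x) < cut)
    },
    stop("configuration error: unregistered symptom construction rule `",
         rule, "`", call. = FALSE)
  )
}

#' Derive domain endorsement from member symptoms
#'
#' A domain is endorsed when any member symptom is endorsed; it is
#' non-endorsed only when every observed member is non-endorsed and at least
#' one member is observed; it is missing only when all members are missing.
#' The any-endorsement rule means an observed 1 dominates missing members.
#'
#' @param members A data frame or matrix of member symptom columns (0/1/`NA`),
#'   one row per participant.
#' @return Integer vector of 0/1/`NA`.
#' @export
derive_domain <- function(members) {
  m <- as.matrix(members)
  if (ncol(m) < 1L) stop_field("members", "needs at least one member symptom")
  any1 <- rowSums(m == 1L, na.rm = TRUE) > 0
  n_obs <- rowSums(!is.na(m))
  out <- as.integer(any1)
  out[!any1 & n_obs == 0L] <- NA_integer_
  out
}

#' Append derived phenotype columns to a cohort
#'
#' Applies every catalog entry to the cohort: symptom entries through their
#' registered construction rule on the named item column, then domain entries
#' as any-endorsement over their member symptoms. Derived columns are named
#' `phen_<phenotype_id>` so raw item columns are left untouched. ACE columns
#' (`any_ace`, `ace_count`, type flags) are appended as well.
#'
#' @param cohort A cohort table with item columns and CTS-5 items.
#' @param catalog A [phenotype_catalog()].
#' @return The cohort with appended `any_ace`, `ace_count`, ACE type flags,
#'   and one `phen_*` column per catalog entry; the ACE exclusion record is
#'   carried in the `"exclusions"` attribute.
#' @export
derive_phenotypes <- function(cohort, catalog) {
  ace <- derive_ace(cohort)
  for (cl in names(ace)) cohort[[cl]] <- ace[[cl]]
  sym <- catalog[catalog$level %in% c("symptom", "both"), ]
  for (i in seq_len(nrow(sym))) {
    item <- sym$members[[i]][1]
    if (!item %in% names(cohort))
      stop("configuration error: item column `", item, "` for phenotype `",
           sym$phenotype_id[i], "` not found in cohort", call. = FALSE)
    cohort[[paste0("phen_", sym$phenotype_id[i])]] <-
      derive_symptom(cohort[[item]], sym$rule[i], sym$rule_param[i])
  }
  dom <- catalog[catalog$level == "domain", ]
  for (i in seq_len(nrow(dom))) {
    mcols <- paste0("phen_", dom$members[[i]])
    cohort[[paste0("phen_", dom$phenotype_id[i])]] <-
      derive_domain(cohort[mcols])
  }
  attr(cohort, "exclusions") <- attr(ace, "exclusions")
  cohort
}
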