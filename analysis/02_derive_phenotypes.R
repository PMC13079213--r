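#!/usr/bin/env Rscript

# Step 2: derive exposures and phenotypes.
#
# Reads the simulated cohort, derives ACE status from the five CTS-5 items,
# aggregates the per-threshold polygenic scores by PRS-PCA with top-quartile
# dichotomization, and constructs every catalog phenotype (symptoms, then
# any-endorsement domains). Writes the analysis-ready cohort and a short
# descriptive summary.

suppressPackageStartupMessages(library(psygxe))

out_dir <- "results/analysis"
cohort <- read_cohort(file.path(out_dir, "cohort.tsv"))
catalog <- read_catalog(file.path(out_dir, "catalog.json"))

prepared <- prepare_cohort(cohort, catalog)
write_cohort(prepared, file.path(out_dir, "cohort_prepared.tsv"))

phen_cols <- paste0("phen_", catalog$phenotype_id)
summary <- tibble::tibble(
  phenotype = catalog$phenotype_id,
  domain = catalog$domain,
  level = catalog$level,
  prevalence = vapply(phen_cols, function(cl) mean(prepared[[cl]], na.rm = TRUE), 0)
)
utils::write.table(summary, file.path(out_dir, "phenotype_prevalence.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("any ACE: %.1f%%; mean ACE count: %.2f\n",
            100 * mean(prepared$any_ace), mean(prepared$ace_count)))
for (d in c("scz", "bip")) {
  hi <- prepared[[paste0("prs_", d, "_high")]]
  cat(sprintf("PRS-%s high (top quartile): %.1f%%\n", toupper(d), 100 * mean(hi)))
}
cat(sprintf("phenotype prevalences span %.3f-%.3f across %d phenotypes\n",
            min(summary$prevalence), max(summary$prevalence), nrow(summary)))
cat("wrote cohort_prepared.tsv and phenotype_prevalence.tsv\n")
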