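#!/usr/bin/env Rscript

# Step 3: univariate screening.
#
# Fits one covariate-adjusted logistic model per phenotype x exposure
# (PRS-SCZ, PRS-BIP, ACE), applies the Bonferroni tier alpha / (61 x 3),
# and selects for the downstream stages the phenotypes significant for
# BOTH a PRS and ACE.

suppressPackageStartupMessages(library(psygxe))

out_dir <- "results/analysis"
cohort <- read_cohort(file.path(out_dir, "cohort_prepared.tsv"))
catalog <- read_catalog(file.path(out_dir, "catalog.json"))
config <- pipeline_config(seed = 20260401)

screen <- run_univariate_screen(cohort, catalog, config)

utils::write.table(screen$results, file.path(out_dir, "univariate_screen.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(screen$selection, file.path(out_dir, "selection.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(screen$log, file.path(out_dir, "screen_log.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("screened %d phenotypes x 3 exposures at alpha = %.3g\n",
            nrow(catalog), screen$alpha_univariate))
sel <- screen$selection[screen$selection$selected_for_joint, ]
for (p in c("prs_scz", "prs_bip"))
  cat(sprintf("selected for %s (significant for both PRS and ACE): %d\n",
              p, sum(sel$prs == p)))
excl <- screen$log[screen$log$status == "excluded", ]
cat(sprintf("models excluded (flagged or degenerate): %d\n", nrow(excl)))
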