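#!/usr/bin/env Rscript
# Univariable two-sample MR of the exposure on each outcome cohort and on
# the fixed-effects pooled outcome: multiplicative random-effects IVW as the
# primary model, with MR-Egger (plus intercept test), weighted median,
# weighted mode and MR-PRESSO as sensitivity estimators.

suppressPackageStartupMessages(library(mrflow))

seed <- 20260922L
data_dir <- file.path("results", "data")
out_dir <- file.path("results", "univariable")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

instruments <- read_summary(file.path("results", "instruments", "instruments.tsv"),
                            trait_id = "exposure")
outcomes <- lapply(1:3, function(i) {
  read_summary(file.path(data_dir, sprintf("outcome_%d.tsv", i)),
               trait_id = paste0("outcome_", i))
})
names(outcomes) <- paste0("outcome_", 1:3)

pooled <- pool_datasets(outcomes, trait_id = "pooled")
cat(sprintf("Pooled %d SNPs across %d cohorts (%d dropped)\n",
            pooled$audit$n_pooled, length(outcomes),
            pooled$audit$n_dropped_irreconcilable))
write_summary(pooled$records, file.path(out_dir, "pooled_outcome.tsv"))

targets <- c(outcomes, list(pooled = pooled$records))
all_rows <- list()
for (nm in names(targets)) {
  set <- harmonize(instruments, targets[[nm]])
  ests <- mr_all(set, bootstrap_reps = 1000, seed = seed)
  pres <- mr_presso(set, n_simulations = 1000, seed = seed + 1)
  corrected <- if (is.null(pres$theta_corrected)) pres$theta_raw else pres$theta_corrected
  ests$presso <- mr_estimate("presso", corrected$theta, corrected$se,
                             corrected$n_snps,
                             extras = list(global_p = pres$global_p,
                                           n_outliers = length(pres$outlier_ids)))
  tab <- estimates_table(ests)
  tab$outcome <- nm
  tab$significance <- label_significance(tab$pvalue)
  all_rows[[nm]] <- tab
  estimates_json(ests, file.path(out_dir, sprintf("estimates_%s.json", nm)))

  ivw <- ests$ivw_mre
  cat(sprintf("%s: IVW-MRE OR = %.3f [%.3f, %.3f], p = %.3g (%s); Egger intercept p = %.2f\n",
              nm, exp(ivw$theta), exp(ivw$ci_low), exp(ivw$ci_high),
              ivw$pvalue, label_significance(ivw$pvalue),
              ests$egger$extras$intercept_p))
}
report <- do.call(rbind, all_rows)
rownames(report) <- NULL
write.table(report, file.path(out_dir, "univariable_mr.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Results table written to", file.path(out_dir, "univariable_mr.tsv"), "\n")
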