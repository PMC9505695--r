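#!/usr/bin/env Rscript
# Build the synthetic study that stands in for the restricted-access GWAS
# data: a large exposure GWAS (184 independent instruments explaining 4% of
# a rank-normalized, variance-1 exposure in 417,580 individuals), three
# independent case-control outcome GWASs over the same instrument panel, and
# a mediation chain (exposure -> mediator -> outcome) with known path
# coefficients. Everything downstream reads the files written here.

suppressPackageStartupMessages(library(mrflow))

seed <- 20260922L
out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# n_reverse SNPs are genuine outcome loci (no effect on the exposure,
# reverse_beta = 0): they never pass exposure-side instrument selection but
# give the reverse analysis real instruments to work with
base <- simulate_two_sample(sim_config(theta = log(0.916), flip_fraction = 0,
                                       n_outcome = 196452, n_snps = 196,
                                       n_reverse = 12, reverse_beta = 0,
                                       seed = seed))
write_simulation(base, out_dir, prefix = "study")

# three non-overlapping outcome datasets: same true SNP-outcome effects,
# independent estimation noise (as three cohorts measuring one disease)
for (i in 1:3) {
  o <- base$outcome
  set.seed(seed + i)
  o$beta <- rnorm(nrow(o), base$truth$gamma_outcome, o$se)
  o$pvalue <- pmax(2 * pnorm(-abs(o$beta / o$se)), .Machine$double.xmin)
  o$trait_id <- paste0("outcome_", i)
  write_summary(o, file.path(out_dir, sprintf("outcome_%d.tsv", i)))
}

chain <- simulate_mediation_chain(seed = seed)
write_simulation(chain, out_dir, prefix = "chain")

cat("Simulated study written to", out_dir, "\n")
cat(sprintf("  exposure: %d SNPs, n = %d\n", nrow(base$exposure),
            unique(base$exposure$n)))
cat(sprintf("  outcomes: 3 cohorts of n = %d (%.1f%% cases)\n",
            unique(base$outcome$n),
            100 * unique(base$outcome$n_cases) / unique(base$outcome$n)))
cat(sprintf("  mediation chain: %d exposure + %d mediator instruments\n",
            length(chain$truth$exposure_snp_ids),
            length(chain$truth$mediator_snp_ids)))
cat(sprintf("  true causal log-odds per SD exposure: %.4f (OR %.3f)\n",
            base$truth$theta, exp(base$truth$theta)))
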