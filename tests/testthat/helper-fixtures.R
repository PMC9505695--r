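# Shared fixture builders. Everything is generated in code; no data files.

# Minimal harmonized set from raw effect vectors.
make_set <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                     n_exposure = 1e5, n_outcome = 1e5,
                     ids = sprintf("snp%05d", seq_along(beta_exposure))) {
  harmonized_set(data.frame(
    variant_id = ids,
    chrom = rep_len(as.character(1:22), length(ids)),
    pos = 1e6 * seq_along(ids),
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf = 0.3, n_exposure = n_exposure, n_outcome = n_outcome,
    stringsAsFactors = FALSE))
}

# Small summary-statistic table with overridable fields.
make_records <- function(n = 5, ...) {
  rec <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(n)),
    chrom = rep_len(as.character(c(1:5, 7:22)), n),
    pos = 1e6 * seq_len(n),
    effect_allele = rep_len(c("A", "G", "C", "T"), n),
    other_allele = rep_len(c("G", "A", "T", "C"), n),
    eaf = rep_len(c(0.2, 0.4, 0.35), n),
    beta = rep_len(c(0.02, -0.03, 0.05), n),
    se = 0.004,
    pvalue = rep_len(c(1e-9, 1e-10, 1e-12), n),
    n = 1e5, n_cases = NA_real_, trait_id = "test_trait",
    stringsAsFactors = FALSE)
  override <- list(...)
  for (nm in names(override)) rec[[nm]] <- override[[nm]]
  rec
}

# Rebuild exposure/outcome record tables from a harmonized set (used to
# check harmonization idempotence).
set_to_records <- function(set) {
  s <- set$snps
  base <- data.frame(
    variant_id = s$variant_id, chrom = s$chrom, pos = s$pos,
    effect_allele = s$effect_allele, other_allele = s$other_allele,
    stringsAsFactors = FALSE)
  exposure <- cbind(base, data.frame(
    eaf = s$eaf, beta = s$beta_exposure, se = s$se_exposure,
    pvalue = s$pvalue_exposure, n = s$n_exposure, n_cases = NA_real_,
    trait_id = set$exposure_id, stringsAsFactors = FALSE))
  outcome <- cbind(base, data.frame(
    eaf = s$eaf_outcome, beta = s$beta_outcome, se = s$se_outcome,
    pvalue = s$pvalue_outcome, n = s$n_outcome, n_cases = s$n_cases_outcome,
    trait_id = set$outcome_id, stringsAsFactors = FALSE))
  list(exposure = exposure, outcome = outcome)
}
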