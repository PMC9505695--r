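# Fixed-effects inverse-variance meta-analysis of per-SNP effects across
# non-overlapping outcome datasets.

#' Fixed-effects inverse-variance pooling of one SNP's effects
#'
#' `w_i = 1/se_i^2`, pooled `beta = sum(w b) / sum(w)`,
#' `se = (sum w)^(-1/2)`, two-sided normal p. Associative: pooling pooled
#' results equals pooling all inputs at once.
#'
#' @param beta,se vectors of per-dataset effects and SEs (>= 1).
#' @return list with `beta`, `se`, `pvalue`, `k` (number of effects pooled).
#' @export
meta_fixed <- function(beta, se) {
  if (length(beta) == 0) stopf("meta_fixed needs at least one effect")
  if (length(se) != length(beta)) stopf("beta and se lengths differ")
  if (any(se <= 0)) stopf("all standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta = b, se = s, pvalue = p_from_z(b / s), k = length(beta))
}

#' Pool outcome datasets into one summary file
#'
#' Aligns every dataset's alleles to the first dataset carrying each SNP
#' (sign flips for swapped or strand-complement allele pairs, exactly as in
#' [harmonize()]), applies [meta_fixed()] per SNP, and records which datasets
#' contributed. SNPs present in only a subset of datasets are pooled over
#' that subset with their presence mask flagged; SNPs with irreconcilable
#' alleles in some dataset are dropped entirely and listed in the audit.
#'
#' @param datasets named list of validated summary-statistic data frames
#'   (each from a dataset with no sample overlap against the others).
#' @param trait_id trait id stored on the pooled records.
#' @return list with `records` (pooled summary table carrying extra columns
#'   `n_datasets` and `dataset_mask`) and `audit` (dropped SNP ids, counts).
#' @export
pool_datasets <- function(datasets, trait_id = "pooled") {
  stopifnot(length(datasets) >= 1)
  names(datasets) <- names(datasets) %||% paste0("dataset_", seq_along(datasets))
  for (d in datasets) validate_summary(d)
  all_ids <- unique(unlist(lapply(datasets, `[[`, "variant_id")))
  dropped <- character(0)
  rows <- vector("list", length(all_ids))

  for (i in seq_along(all_ids)) {
    id <- all_ids[i]
    entries <- lapply(datasets, function(d) d[d$variant_id == id, , drop = FALSE])
    present <- vapply(entries, nrow, 1L) > 0
    entries <- lapply(entries[present], function(e) e[1, , drop = FALSE])
    ref <- entries[[1]]
    beta <- numeric(0); se <- numeric(0); eaf <- numeric(0); n <- numeric(0)
    nc <- 0; has_nc <- FALSE
    ok <- TRUE
    for (e in entries) {
      same <- e$effect_allele == ref$effect_allele & e$other_allele == ref$other_allele
      swap <- e$effect_allele == ref$other_allele & e$other_allele == ref$effect_allele
      comp_same <- dna_complement(e$effect_allele) == ref$effect_allele &
        dna_complement(e$other_allele) == ref$other_allele
      comp_swap <- dna_complement(e$effect_allele) == ref$other_allele &
        dna_complement(e$other_allele) == ref$effect_allele
      if (!(same || swap || comp_same || comp_swap)) { ok <- FALSE; break }
      flip <- !same && !comp_same
      beta <- c(beta, if (flip) -e$beta else e$beta)
      se <- c(se, e$se)
      eaf <- c(eaf, if (flip) 1 - e$eaf else e$eaf)
      n <- c(n, e$n)
      if (!is.na(e$n_cases)) { nc <- nc + e$n_cases; has_nc <- TRUE }
    }
    if (!ok) { dropped <- c(dropped, id); next }
    pooled <- meta_fixed(beta, se)
    rows[[i]] <- data.frame(
      variant_id = id, chrom = ref$chrom, pos = ref$pos,
      effect_allele = ref$effect_allele, other_allele = ref$other_allele,
      eaf = sum(eaf * n) / sum(n),
      beta = pooled$beta, se = pooled$se, pvalue = pooled$pvalue,
      n = sum(n), n_cases = if (has_nc) nc else NA_real_,
      trait_id = trait_id,
      n_datasets = pooled$k,
      dataset_mask = paste(as.integer(present), collapse = ""),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(records) <- NULL
  list(records = records,
       audit = list(n_input_snps = length(all_ids),
                    n_pooled = nrow(records),
                    n_dropped_irreconcilable = length(dropped),
                    dropped_ids = dropped,
                    datasets = names(datasets)))
}
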