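# Reading, validation, filtering, clumping and harmonization of GWAS
# summary statistics.

REQUIRED_FIELDS <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pvalue", "n")

#' Default column mapping for summary-statistic files
#'
#' Maps the package's internal field names to the column headers used in the
#' tab-separated summary-statistic dialect (`SNP`, `CHR`, `POS`, `EA`, `OA`,
#' `EAF`, `BETA`, `SE`, `P`, `N`, `N_CASES`).
#'
#' @return Named character vector: internal field -> file column.
#' @export
default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pvalue = "P", n = "N", n_cases = "N_CASES")
}

normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Validate a table of summary-statistic records
#'
#' Checks the per-record invariants: positive standard errors, allele
#' frequencies strictly inside (0, 1), p-values in (0, 1], positions >= 1,
#' distinct single-nucleotide alleles, and `n >= n_cases` where a case count
#' is present. Throws an error naming the offending row numbers.
#'
#' @param records data frame of summary-statistic records.
#' @return `records`, invisibly, when all checks pass.
#' @export
validate_summary <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(REQUIRED_FIELDS, names(records))
  if (length(missing_cols) > 0) {
    stopf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  }
  bad <- function(cond) which(is.na(cond) | cond)
  problems <- list(
    "se <= 0"              = bad(records$se <= 0),
    "eaf outside (0,1)"    = bad(records$eaf <= 0 | records$eaf >= 1),
    "pvalue outside (0,1]" = bad(records$pvalue <= 0 | records$pvalue > 1),
    "pos < 1"              = bad(records$pos < 1),
    "invalid alleles"      = which(
      !grepl("^[ACGT]$", records$effect_allele) |
        !grepl("^[ACGT]$", records$other_allele) |
        records$effect_allele == records$other_allele),
    "beta not finite"      = bad(!is.finite(records$beta))
  )
  if (!is.null(records$n_cases)) {
    nc <- records$n_cases
    problems[["n < n_cases"]] <- which(!is.na(nc) & records$n < nc)
  }
  problems <- problems[vapply(problems, length, 1L) > 0]
  if (length(problems) > 0) {
    msg <- vapply(names(problems), function(k) {
      rows <- problems[[k]]
      shown <- paste(utils::head(rows, 10), collapse = ", ")
      if (length(rows) > 10) shown <- paste0(shown, ", ...")
      sprintf("%s at row(s) %s", k, shown)
    }, "")
    stopf("invalid summary statistics:\n  %s", paste(msg, collapse = "\n  "))
  }
  invisible(records)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-separated summary-statistic file, renames columns according to
#' `column_map`, coerces types and validates every record. Malformed rows are
#' reported with their row numbers.
#'
#' @param path path to a tab-separated file with one header row.
#' @param column_map named character vector mapping internal field names to
#'   file column headers; see [default_column_map()]. The `n_cases` entry is
#'   optional.
#' @param trait_id identifier stored in the `trait_id` column; defaults to the
#'   file name without extension.
#' @return data frame of validated summary-statistic records.
#' @export
read_summary <- function(path, column_map = default_column_map(),
                         trait_id = NULL) {
  if (!file.exists(path)) stopf("summary file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- setdiff(REQUIRED_FIELDS, "n_cases")
  for (field in mandatory) {
    if (!column_map[[field]] %in% names(raw)) {
      stopf("configuration error: column '%s' (field '%s') not found in %s",
            column_map[[field]], field, path)
    }
  }
  records <- data.frame(
    variant_id    = as.character(raw[[column_map[["variant_id"]]]]),
    chrom         = normalize_chrom(raw[[column_map[["chrom"]]]]),
    pos           = as.numeric(raw[[column_map[["pos"]]]]),
    effect_allele = toupper(as.character(raw[[column_map[["effect_allele"]]]])),
    other_allele  = toupper(as.character(raw[[column_map[["other_allele"]]]])),
    eaf           = as.numeric(raw[[column_map[["eaf"]]]]),
    beta          = as.numeric(raw[[column_map[["beta"]]]]),
    se            = as.numeric(raw[[column_map[["se"]]]]),
    pvalue        = as.numeric(raw[[column_map[["pvalue"]]]]),
    n             = as.numeric(raw[[column_map[["n"]]]]),
    stringsAsFactors = FALSE
  )
  nc_col <- column_map["n_cases"]
  records$n_cases <- if (!is.na(nc_col) && nc_col %in% names(raw)) {
    as.numeric(raw[[nc_col]])
  } else {
    NA_real_
  }
  records$trait_id <- trait_id %||% tools::file_path_sans_ext(basename(path))
  validate_summary(records)
  records
}

#' Write summary statistics to a tab-separated file
#'
#' Inverse of [read_summary()]: emits the standard summary-statistic dialect.
#' Extra columns beyond the mapped fields (e.g. pooling provenance) are
#' appended unchanged.
#'
#' @param records data frame of summary-statistic records.
#' @param path output path.
#' @param column_map named character vector, see [default_column_map()].
#' @return `path`, invisibly.
#' @export
write_summary <- function(records, path, column_map = default_column_map()) {
  out <- records
  fields <- intersect(names(column_map), names(out))
  extra <- setdiff(names(out), c(names(column_map), "trait_id"))
  out <- out[, c(fields, extra), drop = FALSE]
  names(out)[seq_along(fields)] <- column_map[fields]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' The HLA exclusion region
#'
#' The extended human leukocyte antigen region on chromosome 6
#' (25–34 Mb, 1-based closed interval), conventionally excluded from
#' instrument sets because of its long-range LD and dense pleiotropy.
#'
#' @return One-row data frame with columns `chrom`, `start`, `end`.
#' @export
hla_region <- function() {
  data.frame(chrom = "6", start = 25e6, end = 34e6, stringsAsFactors = FALSE)
}

in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(chrom))
  if (is.null(regions) || nrow(regions) == 0) return(hit)
  rc <- normalize_chrom(regions$chrom)
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == rc[i] & pos >= regions$start[i] & pos <= regions$end[i])
  }
  hit
}

#' Filter candidate instruments
#'
#' Applies the standard instrument-selection filters sequentially: association
#' p-value below `p_threshold`, minor allele frequency (`min(eaf, 1 - eaf)`)
#' at least `maf_min`, removal of multiallelic variants (any `variant_id`
#' occurring more than once), removal of palindromic variants (allele pair
#' A/T or C/G), and exclusion of closed genomic intervals such as
#' [hla_region()]. An audit list counts the records removed by each filter;
#' the counts plus the retained count always sum to the input count.
#'
#' @param records data frame of summary-statistic records.
#' @param p_threshold keep records with `pvalue < p_threshold`.
#' @param maf_min minimum minor allele frequency.
#' @param drop_palindromic,drop_multiallelic logical toggles.
#' @param exclusion_regions data frame with columns `chrom`, `start`, `end`
#'   (1-based closed intervals), or `NULL`.
#' @return list with elements `records` (retained rows) and `audit`
#'   (named counts, plus `empty` flag).
#' @export
filter_instruments <- function(records, p_threshold = 5e-8, maf_min = 0.01,
                               drop_palindromic = TRUE, drop_multiallelic = TRUE,
                               exclusion_regions = NULL) {
  validate_summary(records)
  if (p_threshold <= 0 || p_threshold >= 1) {
    stopf("p_threshold must be in (0,1), got %g", p_threshold)
  }
  audit <- list(n_input = nrow(records))
  keep <- records

  drop_p <- keep$pvalue >= p_threshold
  audit$n_pvalue <- sum(drop_p)
  keep <- keep[!drop_p, , drop = FALSE]

  maf <- pmin(keep$eaf, 1 - keep$eaf)
  drop_maf <- maf < maf_min
  audit$n_maf <- sum(drop_maf)
  keep <- keep[!drop_maf, , drop = FALSE]

  if (drop_multiallelic) {
    dup_ids <- unique(keep$variant_id[duplicated(keep$variant_id)])
    drop_multi <- keep$variant_id %in% dup_ids
  } else {
    drop_multi <- rep(FALSE, nrow(keep))
  }
  audit$n_multiallelic <- sum(drop_multi)
  keep <- keep[!drop_multi, , drop = FALSE]

  if (drop_palindromic) {
    drop_pal <- is_palindromic(keep$effect_allele, keep$other_allele)
  } else {
    drop_pal <- rep(FALSE, nrow(keep))
  }
  audit$n_palindromic <- sum(drop_pal)
  keep <- keep[!drop_pal, , drop = FALSE]

  drop_region <- in_regions(keep$chrom, keep$pos, exclusion_regions)
  audit$n_region <- sum(drop_region)
  keep <- keep[!drop_region, , drop = FALSE]

  audit$n_retained <- nrow(keep)
  audit$empty <- nrow(keep) == 0
  rownames(keep) <- NULL
  list(records = keep, audit = audit)
}

#' Validate an LD matrix
#'
#' @param r2 square numeric matrix of squared correlations with variant ids as
#'   dimnames.
#' @return `r2`, invisibly.
#' @export
validate_ld_matrix <- function(r2) {
  if (!is.matrix(r2) || nrow(r2) != ncol(r2)) stopf("LD matrix must be square")
  if (is.null(rownames(r2)) || is.null(colnames(r2)) ||
      !identical(rownames(r2), colnames(r2))) {
    stopf("LD matrix needs identical row and column variant ids")
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) stopf("LD matrix diagonal must be 1")
  if (any(r2 < -1e-8 | r2 > 1 + 1e-8)) stopf("LD r2 values must lie in [0,1]")
  if (any(abs(r2 - t(r2)) > 1e-8)) stopf("LD matrix must be symmetric")
  invisible(r2)
}

#' Read / write a pairwise-LD matrix
#'
#' Tab-separated square matrix with variant ids as the header row and first
#' column.
#'
#' @param path file path.
#' @return For `read_ld_matrix`, a validated numeric matrix.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  r2 <- as.matrix(raw)
  validate_ld_matrix(r2)
  r2
}

#' @rdname read_ld_matrix
#' @param r2 square LD matrix with dimnames.
#' @export
write_ld_matrix <- function(r2, path) {
  validate_ld_matrix(r2)
  out <- data.frame(SNP = rownames(r2), r2, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy LD clumping
#'
#' Repeatedly selects the remaining record with the smallest p-value (ties
#' broken by lexicographic `variant_id`) and discards all remaining records on
#' the same chromosome within `window_kb` kilobases whose squared correlation
#' with it is at least `r2_threshold`. Variants on different chromosomes are
#' never clumped against each other.
#'
#' @param records data frame of summary-statistic records.
#' @param ld LD matrix covering every `variant_id` in `records`.
#' @param r2_threshold discard correlated neighbours with `r2 >= r2_threshold`.
#' @param window_kb window half-width in kilobases, measured between `pos`
#'   values.
#' @return Retained records, in selection order.
#' @export
clump <- function(records, ld, r2_threshold = 0.01, window_kb = 10000) {
  validate_summary(records)
  validate_ld_matrix(ld)
  missing <- setdiff(records$variant_id, rownames(ld))
  if (length(missing) > 0) {
    stopf("variant(s) missing from LD matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  remaining <- records[order(records$pvalue, records$variant_id), , drop = FALSE]
  selected <- integer(0)
  sel_rows <- list()
  while (nrow(remaining) > 0) {
    top <- remaining[1, , drop = FALSE]
    sel_rows[[length(sel_rows) + 1L]] <- top
    rest <- remaining[-1, , drop = FALSE]
    if (nrow(rest) == 0) break
    same_chr <- rest$chrom == top$chrom
    near <- same_chr & abs(rest$pos - top$pos) <= window_kb * 1000
    r2_with_top <- ld[top$variant_id, rest$variant_id]
    drop <- near & (r2_with_top >= r2_threshold)
    remaining <- rest[!drop, , drop = FALSE]
  }
  out <- do.call(rbind, sel_rows)
  rownames(out) <- NULL
  out
}

dna_complement <- function(x) chartr("ACGT", "TGCA", x)

#' Construct a harmonized instrument set
#'
#' Low-level constructor validating the invariants of the allele-aligned
#' per-SNP effect table consumed by every estimator: unique variant ids and
#' strictly positive standard errors on both sides.
#'
#' @param snps data frame with columns `variant_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, and optionally `chrom`,
#'   `pos`, `eaf`, `n_exposure`, `n_outcome`.
#' @param exposure_id,outcome_id trait identifiers.
#' @param provenance named list of harmonization counts.
#' @return Object of class `harmonized_set`.
#' @export
harmonized_set <- function(snps, exposure_id = "exposure",
                           outcome_id = "outcome", provenance = list()) {
  needed <- c("variant_id", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome")
  missing_cols <- setdiff(needed, names(snps))
  if (length(missing_cols) > 0) {
    stopf("harmonized set lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(snps$variant_id)) stopf("duplicate variant_id in harmonized set")
  if (nrow(snps) > 0 && (any(snps$se_exposure <= 0) || any(snps$se_outcome <= 0))) {
    stopf("all standard errors in a harmonized set must be positive")
  }
  rownames(snps) <- NULL
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 snps = snps, provenance = provenance),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %s -> %s (%d SNPs)\n",
              x$exposure_id, x$outcome_id, nrow(x$snps)))
  if (length(x$provenance) > 0) {
    cat("  provenance:",
        paste(sprintf("%s=%s", names(x$provenance), unlist(x$provenance)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Number of SNPs in a harmonized set.
n_snps <- function(set) nrow(set$snps)

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two record tables on `variant_id` and aligns outcome effects
#' onto the exposure's effect allele. Outcome records whose alleles are
#' swapped relative to the exposure (directly or as strand complements) have
#' their `beta` negated and `eaf` replaced by `1 - eaf`. Palindromic variants
#' are dropped under `palindrome_policy = "drop"` (they are strand-ambiguous);
#' allele pairs that cannot be reconciled are dropped and counted.
#'
#' @param exposure,outcome validated summary-statistic data frames.
#' @param palindrome_policy `"drop"` (default) or `"keep"` (treat as
#'   same-strand).
#' @return A [harmonized_set()] with provenance counts
#'   (`n_sign_flipped`, `n_palindromic_dropped`, `n_unmatched_dropped`, ...).
#' @export
harmonize <- function(exposure, outcome, palindrome_policy = c("drop", "keep")) {
  palindrome_policy <- match.arg(palindrome_policy)
  validate_summary(exposure)
  validate_summary(outcome)
  exposure <- exposure[!duplicated(exposure$variant_id), , drop = FALSE]
  outcome <- outcome[!duplicated(outcome$variant_id), , drop = FALSE]
  common <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(common) == 0) stopf("no overlapping variants between exposure and outcome")
  ex <- exposure[match(common, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(common, outcome$variant_id), , drop = FALSE]

  same      <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swap      <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  comp_same <- dna_complement(ou$effect_allele) == ex$effect_allele &
               dna_complement(ou$other_allele) == ex$other_allele
  comp_swap <- dna_complement(ou$effect_allele) == ex$other_allele &
               dna_complement(ou$other_allele) == ex$effect_allele
  pal <- is_palindromic(ex$effect_allele, ex$other_allele) |
         is_palindromic(ou$effect_allele, ou$other_allele)

  drop_pal <- pal & palindrome_policy == "drop"
  # For palindromes kept, direct allele identity decides orientation
  # (complement matching is uninformative for them).
  flip <- ifelse(pal, swap, (!same & !comp_same) & (swap | comp_swap))
  matched <- same | swap | comp_same | comp_swap
  keep <- matched & !drop_pal

  beta_outcome <- ifelse(flip, -ou$beta, ou$beta)
  eaf_outcome <- ifelse(flip, 1 - ou$eaf, ou$eaf)

  snps <- data.frame(
    variant_id = common,
    chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf = ex$eaf,
    beta_exposure = ex$beta, se_exposure = ex$se,
    pvalue_exposure = ex$pvalue, n_exposure = ex$n,
    beta_outcome = beta_outcome, se_outcome = ou$se,
    pvalue_outcome = ou$pvalue, n_outcome = ou$n,
    eaf_outcome = eaf_outcome,
    n_cases_outcome = ou$n_cases,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]

  provenance <- list(
    n_exposure_input = nrow(exposure),
    n_outcome_input = nrow(outcome),
    n_overlap = length(common),
    n_sign_flipped = sum(flip & keep),
    n_palindromic_dropped = sum(drop_pal),
    n_unmatched_dropped = sum(!matched & !drop_pal),
    n_retained = sum(keep)
  )
  if (sum(keep) == 0) stopf("no variants retained after harmonization")
  harmonized_set(snps,
                 exposure_id = ex$trait_id[1] %||% "exposure",
                 outcome_id = ou$trait_id[1] %||% "outcome",
                 provenance = provenance)
}

#' Restrict a harmonized set to (or drop) a vector of variant ids
#'
#' @param set a [harmonized_set()].
#' @param keep_ids,drop_ids variant ids to retain / remove.
#' @return The filtered [harmonized_set()].
#' @export
subset_set <- function(set, keep_ids = NULL, drop_ids = NULL) {
  snps <- set$snps
  if (!is.null(keep_ids)) snps <- snps[snps$variant_id %in% keep_ids, , drop = FALSE]
  if (!is.null(drop_ids)) snps <- snps[!snps$variant_id %in% drop_ids, , drop = FALSE]
  harmonized_set(snps, set$exposure_id, set$outcome_id, set$provenance)
}
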