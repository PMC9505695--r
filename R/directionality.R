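# Steiger directionality test and filtering against reverse causation.

#' Squared trait correlation from summary statistics
#'
#' Standard t-to-r conversion: with `t = beta/se`, `r2 = t^2 / (t^2 + n - 2)`.
#' For binary outcomes the same formula is applied to the logistic-scale
#' statistics; this is an approximation (the liability-scale conversion is a
#' possible refinement) and is how the filter treats case-control traits
#' throughout.
#'
#' @param beta,se effect estimate and SE (vectorized).
#' @param n sample size (> 2).
#' @return Squared correlation in `[0, 1)`.
#' @export
r2_from_summary <- function(beta, se, n) {
  if (any(n <= 2)) stopf("r2_from_summary requires n > 2")
  if (any(se <= 0)) stopf("se must be positive")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Steiger test for causal direction
#'
#' Compares the instrument's correlation with the exposure against its
#' correlation with the outcome via Fisher z-transforms:
#' `z = (atanh(r_exposure) - atanh(r_outcome)) / sqrt(1/(n_exp - 3) +
#' 1/(n_out - 3))`, two-sided normal p. `direction_true` holds when the
#' instrument explains more variance in the exposure than in the outcome.
#'
#' @param r2_exposure,r2_outcome squared correlations in `[0, 1)` (vectorized).
#' @param n_exposure,n_outcome sample sizes (> 3).
#' @return list with vectors `direction_true` and `steiger_p`.
#' @export
steiger_test <- function(r2_exposure, n_exposure, r2_outcome, n_outcome) {
  if (any(r2_exposure < 0 | r2_exposure >= 1) ||
      any(r2_outcome < 0 | r2_outcome >= 1)) {
    stopf("r2 values must lie in [0,1)")
  }
  if (any(n_exposure <= 3) || any(n_outcome <= 3)) stopf("sample sizes must exceed 3")
  z_exp <- atanh(sqrt(r2_exposure))
  z_out <- atanh(sqrt(r2_outcome))
  se <- sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  z <- (z_exp - z_out) / se
  list(direction_true = r2_exposure > r2_outcome, steiger_p = p_from_z(z))
}

#' Per-SNP Steiger records for a harmonized set
#'
#' @param set a [harmonized_set()] with sample sizes on both sides.
#' @return data frame with `variant_id`, `r2_exposure`, `r2_outcome`,
#'   `direction_true`, `steiger_p`.
#' @export
steiger_records <- function(set) {
  s <- set$snps
  if (any(is.na(s$n_exposure)) || any(is.na(s$n_outcome))) {
    stopf("Steiger filtering needs sample sizes for both traits")
  }
  r2x <- r2_from_summary(s$beta_exposure, s$se_exposure, s$n_exposure)
  r2y <- r2_from_summary(s$beta_outcome, s$se_outcome, s$n_outcome)
  st <- steiger_test(r2x, s$n_exposure, r2y, s$n_outcome)
  data.frame(variant_id = s$variant_id, r2_exposure = r2x, r2_outcome = r2y,
             direction_true = st$direction_true, steiger_p = st$steiger_p,
             stringsAsFactors = FALSE)
}

#' Steiger filtering
#'
#' Retains instruments with `direction_true` (more variance explained in the
#' exposure than the outcome; ties are not retained) and `steiger_p <
#' p_threshold`, removing potential reverse-causal instruments. Idempotent.
#' An empty retained set is flagged in the returned audit, and downstream
#' estimators will refuse it with a clear error.
#'
#' @param set a [harmonized_set()].
#' @param p_threshold retention threshold on the Steiger p (default 0.01).
#' @return list with `set` (filtered [harmonized_set()]) and `records`
#'   (the full per-SNP audit table with a `retained` column).
#' @export
steiger_filter <- function(set, p_threshold = 0.01) {
  rec <- steiger_records(set)
  rec$retained <- rec$direction_true & rec$steiger_p < p_threshold
  filtered <- harmonized_set(set$snps[rec$retained, , drop = FALSE],
                             set$exposure_id, set$outcome_id,
                             c(set$provenance,
                               list(n_steiger_removed = sum(!rec$retained),
                                    steiger_empty = !any(rec$retained))))
  list(set = filtered, records = rec)
}

#' Write Steiger records to TSV
#'
#' @param records data frame from [steiger_filter()] or [steiger_records()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_steiger_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
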