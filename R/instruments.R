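# Instrument-strength and study-design diagnostics.

#' Per-SNP F statistic
#'
#' Instrument strength of a single variant, `beta^2 / se^2`. Values of 10 or
#' more are conventionally taken to indicate adequate strength.
#'
#' @param beta,se effect estimate and its standard error (vectorized).
#' @return Numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stopf("se must be positive")
  (beta / se)^2
}

#' Per-SNP proportion of variance explained
#'
#' `2 * beta^2 * maf * (1 - maf)` with `maf = min(eaf, 1 - eaf)`, valid for a
#' variance-1 quantitative trait with per-allele effect `beta`.
#'
#' @param beta per-allele effect in SD units.
#' @param eaf effect-allele frequency in (0, 1) (vectorized).
#' @return Numeric vector of variance proportions.
#' @export
variance_explained <- function(beta, eaf) {
  if (any(eaf <= 0 | eaf >= 1)) stopf("eaf must lie strictly in (0,1)")
  maf <- pmin(eaf, 1 - eaf)
  2 * beta^2 * maf * (1 - maf)
}

#' I2GX: variability of instrument strength
#'
#' Meta-analytic heterogeneity of the SNP-exposure estimates, quantifying
#' violation of the no-measurement-error (NOME) assumption behind MR-Egger.
#' With weights `w_j = 1/se_j^2` and weighted mean `g`, the statistic is
#' `Q = sum w_j (beta_j - g)^2` and `I2 = max(0, (Q - (J-1))/Q)`. Values near
#' 1 indicate that measurement error in the SNP-exposure effects is
#' negligible relative to their spread.
#'
#' @param beta_exposure,se_exposure SNP-exposure estimates and SEs (>= 2 SNPs).
#' @return list with `i2_gx`, `q`, and `n_snps`.
#' @export
i2_gx <- function(beta_exposure, se_exposure) {
  j <- length(beta_exposure)
  if (j < 2) stopf("i2_gx needs at least 2 SNPs")
  if (any(se_exposure <= 0)) stopf("se must be positive")
  w <- 1 / se_exposure^2
  g <- sum(w * beta_exposure) / sum(w)
  q <- sum(w * (beta_exposure - g)^2)
  i2 <- if (q > 0) max(0, (q - (j - 1)) / q) else 0
  list(i2_gx = i2, q = q, n_snps = j)
}

#' Sample-overlap bias approximation
#'
#' First-order approximation of the bias a confounded exposure-outcome
#' association induces in a two-sample MR estimate when the exposure and
#' outcome samples overlap: `bias = overlap_fraction * confounded_assoc /
#' f_mean`, linear in the overlap fraction and decaying as `1/F`. The relative
#' bias `overlap_fraction / f_mean` does not depend on the confounded
#' association.
#'
#' @param f_mean mean instrument F statistic (> 1).
#' @param overlap_fraction fraction of overlapping samples in `[0, 1]`.
#' @param confounded_assoc the (biased) observational association the
#'   overlapping sample would induce under full overlap.
#' @return list with `bias` and `relative_bias`.
#' @export
overlap_bias <- function(f_mean, overlap_fraction, confounded_assoc = 1) {
  if (f_mean <= 1) stopf("overlap_bias requires f_mean > 1 (instruments too weak)")
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stopf("overlap_fraction must lie in [0,1]")
  }
  rel <- overlap_fraction / f_mean
  list(bias = rel * confounded_assoc, relative_bias = rel)
}

#' Instrument diagnostics report
#'
#' Per-SNP F statistics and variance explained plus the aggregate quantities
#' (total PVE, F range, I2GX) for an instrument table or the exposure side of
#' a harmonized set.
#'
#' @param x data frame with columns `beta`, `se`, `eaf` (and optionally
#'   `variant_id`), or a `harmonized_set`.
#' @return Object of class `instrument_diagnostics`: list with `per_snp`
#'   (data frame) and aggregates `pve_total`, `f_min`, `f_max`, `f_mean`,
#'   `i2_gx`, `n_snps`, `trait_id`.
#' @export
instrument_diagnostics <- function(x) {
  if (inherits(x, "harmonized_set")) {
    df <- data.frame(variant_id = x$snps$variant_id,
                     beta = x$snps$beta_exposure,
                     se = x$snps$se_exposure,
                     eaf = x$snps$eaf, stringsAsFactors = FALSE)
    trait <- x$exposure_id
  } else {
    df <- data.frame(variant_id = x$variant_id %||% as.character(seq_len(nrow(x))),
                     beta = x$beta, se = x$se, eaf = x$eaf,
                     stringsAsFactors = FALSE)
    trait <- x$trait_id[1] %||% "exposure"
  }
  f <- f_statistic(df$beta, df$se)
  pve <- variance_explained(df$beta, df$eaf)
  per_snp <- data.frame(variant_id = df$variant_id, f_stat = f, pve = pve,
                        stringsAsFactors = FALSE)
  i2 <- if (nrow(df) >= 2) i2_gx(df$beta, df$se)$i2_gx else NA_real_
  structure(list(per_snp = per_snp, pve_total = sum(pve),
                 f_min = min(f), f_max = max(f), f_mean = mean(f),
                 i2_gx = i2, n_snps = nrow(df), trait_id = trait),
            class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf("Instrument diagnostics for %s (%d SNPs)\n", x$trait_id, x$n_snps))
  cat(sprintf("  F: min %.1f, mean %.1f, max %.1f\n", x$f_min, x$f_mean, x$f_max))
  cat(sprintf("  total PVE: %.4f  I2GX: %s\n", x$pve_total,
              ifelse(is.na(x$i2_gx), "NA", sprintf("%.4f", x$i2_gx))))
  invisible(x)
}

#' Write instrument diagnostics as JSON
#'
#' @param diag an `instrument_diagnostics` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
diagnostics_json <- function(diag, path) {
  payload <- stats::setNames(list(list(
    n_snps = diag$n_snps, pve_total = diag$pve_total,
    f_min = diag$f_min, f_mean = diag$f_mean, f_max = diag$f_max,
    i2_gx = diag$i2_gx,
    per_snp = diag$per_snp
  )), diag$trait_id)
  write_json_report(payload, path)
}
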