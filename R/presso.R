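# MR-PRESSO: simulation-based global pleiotropy test, per-SNP outlier test,
# outlier-corrected estimate and distortion test.

# Leave-one-out IVW slopes for all SNPs at once. gx, gy, w are vectors.
loo_ivw <- function(gx, gy, w) {
  num <- sum(w * gx * gy)
  den <- sum(w * gx^2)
  (num - w * gx * gy) / (den - w * gx^2)
}

#' MR-PRESSO global pleiotropy test
#'
#' Computes, for each SNP, the IVW slope with that SNP left out and the
#' weighted squared residual of the SNP against it; the observed residual sum
#' of squares is compared to a simulated null in which outcome and exposure
#' effects are redrawn from normal distributions centred on the fitted values
#' (`theta_(-j) * beta_exposure_j`) and the observed exposure effects, with
#' the reported SEs. The empirical p-value uses the add-one convention
#' `(1 + #{RSS* >= RSS_obs}) / (n_simulations + 1)`.
#'
#' @param set a [harmonized_set()] with at least 4 SNPs.
#' @param n_simulations number of simulated datasets (>= 100).
#' @param seed RNG seed (mandatory).
#' @return list with `rss_obs`, `global_p`, per-SNP observed residuals
#'   `r2_obs`, the simulated per-SNP residual matrix `r2_sim`
#'   (n_simulations x J), `n_simulations` and `seed`.
#' @export
presso_global <- function(set, n_simulations = 1000, seed) {
  j <- n_snps(set)
  if (j < 4) stopf("MR-PRESSO needs at least 4 SNPs")
  if (n_simulations < 100) stopf("n_simulations must be at least 100")
  # sort by variant id so the simulated null (hence the p-values) does not
  # depend on input row order
  ord <- order(set$snps$variant_id)
  snps <- set$snps[ord, , drop = FALSE]
  gx <- snps$beta_exposure; sx <- snps$se_exposure
  gy <- snps$beta_outcome; sy <- snps$se_outcome
  w <- 1 / sy^2

  theta_loo <- loo_ivw(gx, gy, w)
  r2_obs <- w * (gy - theta_loo * gx)^2
  rss_obs <- sum(r2_obs)

  r2_sim <- with_seed(seed, {
    mu_y <- theta_loo * gx
    gys <- matrix(stats::rnorm(n_simulations * j, rep(mu_y, each = n_simulations),
                               rep(sy, each = n_simulations)),
                  nrow = n_simulations)
    gxs <- matrix(stats::rnorm(n_simulations * j, rep(gx, each = n_simulations),
                               rep(sx, each = n_simulations)),
                  nrow = n_simulations)
    wm <- matrix(w, nrow = n_simulations, ncol = j, byrow = TRUE)
    num <- rowSums(wm * gxs * gys)
    den <- rowSums(wm * gxs^2)
    theta_loo_s <- (num - wm * gxs * gys) / (den - wm * gxs^2)
    wm * (gys - theta_loo_s * gxs)^2
  })
  rss_sim <- rowSums(r2_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_simulations + 1)

  list(rss_obs = rss_obs, global_p = global_p,
       r2_obs = stats::setNames(r2_obs, snps$variant_id),
       r2_sim = r2_sim, rss_sim = rss_sim, variant_ids = snps$variant_id,
       n_simulations = n_simulations, seed = seed)
}

#' MR-PRESSO outlier test
#'
#' Per-SNP empirical p-values comparing each observed residual to that SNP's
#' simulated residual distribution from [presso_global()]; SNPs with
#' `p < significance / J` (Bonferroni across the J instruments) are flagged
#' and removed to produce the outlier-corrected multiplicative random-effects
#' IVW estimate.
#'
#' @param set the [harmonized_set()] the global test was run on.
#' @param global result of [presso_global()].
#' @param significance family-wise level for the Bonferroni threshold.
#' @return list with `outlier_ids`, per-SNP `outlier_p`, `theta_raw` and
#'   `theta_corrected` ([mr_estimate()]s; `theta_corrected` is `NULL` when
#'   nothing is flagged).
#' @export
presso_outlier <- function(set, global, significance = 0.05) {
  j <- n_snps(set)
  n_sim <- global$n_simulations
  p_snp <- (1 + colSums(global$r2_sim >= rep(global$r2_obs, each = n_sim))) /
    (n_sim + 1)
  flagged <- p_snp < significance / j
  ids <- global$variant_ids[flagged]
  if (all(flagged)) stopf("MR-PRESSO flagged every SNP; no estimable subset remains")
  theta_raw <- mr_ivw(set, mode = "mre")
  theta_corrected <- if (any(flagged)) {
    mr_ivw(subset_set(set, drop_ids = ids), mode = "mre")
  }
  list(outlier_ids = ids,
       outlier_p = stats::setNames(p_snp, global$variant_ids),
       theta_raw = theta_raw, theta_corrected = theta_corrected)
}

#' MR-PRESSO distortion test
#'
#' Observed distortion `(theta_raw - theta_corrected) / theta_corrected`
#' compared to a null distribution obtained by repeatedly removing the same
#' number of SNPs at random and recomputing the IVW estimate; two-sided
#' empirical p with the add-one convention.
#'
#' @param set the full [harmonized_set()].
#' @param outlier_ids flagged variant ids (from [presso_outlier()]).
#' @param n_resamples random removals for the null.
#' @param seed RNG seed.
#' @return list with `applicable`, `distortion`, `distortion_p`.
#' @export
presso_distortion <- function(set, outlier_ids, n_resamples = 1000, seed) {
  if (length(outlier_ids) == 0) {
    return(list(applicable = FALSE, distortion = NA_real_,
                distortion_p = NA_real_))
  }
  j <- n_snps(set)
  k <- length(outlier_ids)
  if (k >= j) stopf("cannot remove all SNPs in the distortion test")
  theta_raw <- mr_ivw(set, mode = "mre")$theta
  theta_corr <- mr_ivw(subset_set(set, drop_ids = outlier_ids), mode = "mre")$theta
  if (theta_corr == 0) stopf("distortion undefined: corrected estimate is zero")
  d_obs <- (theta_raw - theta_corr) / theta_corr
  ids_sorted <- sort(set$snps$variant_id)
  d_null <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      drop <- sample(ids_sorted, k)
      th <- mr_ivw(subset_set(set, drop_ids = drop), mode = "mre")$theta
      (theta_raw - th) / th
    }, 0)
  })
  p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_resamples + 1)
  list(applicable = TRUE, distortion = d_obs, distortion_p = p)
}

#' Run the full MR-PRESSO procedure
#'
#' Global test, outlier test with Bonferroni multiplicity control, the
#' outlier-corrected estimate, and the distortion test.
#'
#' @param set a [harmonized_set()] with at least 4 SNPs.
#' @param n_simulations simulations for the global/outlier tests.
#' @param seed master seed; the distortion test derives its own stream.
#' @param significance family-wise outlier level.
#' @param n_resamples distortion-test resamples.
#' @return Object of class `presso_result` with fields `rss_obs`, `global_p`,
#'   `outlier_ids`, `outlier_p`, `theta_raw`, `theta_corrected`,
#'   `distortion`, `distortion_p`, `n_simulations`, `seed`.
#' @export
mr_presso <- function(set, n_simulations = 1000, seed = 1,
                      significance = 0.05, n_resamples = 1000) {
  glob <- presso_global(set, n_simulations, seed)
  outl <- presso_outlier(set, glob, significance)
  dist <- presso_distortion(set, outl$outlier_ids, n_resamples,
                            seed = derive_seed(seed, 99))
  structure(list(rss_obs = glob$rss_obs, global_p = glob$global_p,
                 outlier_ids = outl$outlier_ids, outlier_p = outl$outlier_p,
                 theta_raw = outl$theta_raw,
                 theta_corrected = outl$theta_corrected,
                 distortion = dist$distortion, distortion_p = dist$distortion_p,
                 n_simulations = n_simulations, seed = seed,
                 significance = significance),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS_obs = %.3f, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_p, x$n_simulations))
  if (length(x$outlier_ids) > 0) {
    cat(sprintf("  outliers (%d): %s\n", length(x$outlier_ids),
                paste(x$outlier_ids, collapse = ", ")))
    cat(sprintf("  corrected theta = %.4f (raw %.4f), distortion p = %.4g\n",
                x$theta_corrected$theta, x$theta_raw$theta, x$distortion_p))
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' Serialize an MR-PRESSO result
#'
#' Writes the result as JSON and, optionally, the flagged variant ids as a
#' plain-text exclusion list (one id per line) consumable by the
#' harmonization/filtering step.
#'
#' @param x a `presso_result`.
#' @param path JSON output path.
#' @param exclusion_path optional plain-text outlier list path.
#' @return `path`, invisibly.
#' @export
presso_json <- function(x, path, exclusion_path = NULL) {
  payload <- list(
    rss_obs = x$rss_obs, global_p = x$global_p,
    outlier_ids = as.list(x$outlier_ids),
    outlier_p = as.list(x$outlier_p),
    theta_raw = x$theta_raw$theta,
    theta_corrected = if (!is.null(x$theta_corrected)) x$theta_corrected$theta,
    distortion = x$distortion, distortion_p = x$distortion_p,
    n_simulations = x$n_simulations, seed = x$seed
  )
  write_json_report(payload, path)
  if (!is.null(exclusion_path)) {
    writeLines(x$outlier_ids, exclusion_path)
  }
  invisible(path)
}
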