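# Univariable two-sample MR estimators on a harmonized instrument set.

#' Construct an MR estimate
#'
#' Internal constructor shared by every estimator. Confidence intervals and
#' p-values come from the normal distribution unless `df` is supplied, in
#' which case the t distribution with `df` degrees of freedom is used.
#'
#' @param method method label.
#' @param theta causal effect per SD exposure (log-odds for binary outcomes).
#' @param se standard error of `theta` (may be `NA` when no bootstrap was run).
#' @param n_snps number of instruments used.
#' @param df degrees of freedom for t-based inference, or `NULL` for normal.
#' @param level confidence level.
#' @param extras method-specific extras (Egger intercept, Q, phi, seeds, ...).
#' @return Object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, theta, se, n_snps, df = NULL, level = 0.95,
                        extras = list()) {
  if (is.na(se)) {
    ci <- c(NA_real_, NA_real_); p <- NA_real_
  } else if (se == 0) {
    # degenerate noise-free fit (e.g. exactly proportional data under the
    # multiplicative model): the interval collapses onto the point estimate
    ci <- c(theta, theta)
    p <- if (theta == 0) 1 else 0
  } else {
    if (se < 0) stopf("mr_estimate: se must be non-negative")
    crit <- if (is.null(df)) stats::qnorm(1 - (1 - level) / 2)
            else stats::qt(1 - (1 - level) / 2, df = df)
    ci <- theta + c(-1, 1) * crit * se
    p <- if (is.null(df)) p_from_z(theta / se) else p_from_t(theta / se, df)
  }
  structure(list(method = method, theta = theta, se = se,
                 ci_low = ci[1], ci_high = ci[2], pvalue = p,
                 n_snps = n_snps, extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: theta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g, %d SNPs\n",
              x$method, x$theta, x$se, exp(x$theta), exp(x$ci_low),
              exp(x$ci_high), x$pvalue, x$n_snps))
  invisible(x)
}

set_weights <- function(set) 1 / set$snps$se_outcome^2

#' Wald ratio estimate for a single instrument
#'
#' `theta = beta_outcome / beta_exposure` with the first-order delta-method
#' standard error `se_outcome / |beta_exposure|` (exposure uncertainty
#' ignored, the dominant convention; a limitation when instruments are weak).
#'
#' @param beta_exposure,se_exposure SNP-exposure effect and SE.
#' @param beta_outcome,se_outcome SNP-outcome effect and SE.
#' @return An [mr_estimate()] with method `"wald"`.
#' @export
mr_wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  if (beta_exposure == 0) stopf("wald ratio undefined for beta_exposure = 0")
  theta <- beta_outcome / beta_exposure
  se <- se_outcome / abs(beta_exposure)
  mr_estimate("wald", theta, se, n_snps = 1)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_outcome^2`. The fixed-effects SE is
#' `(sum w beta_exposure^2)^(-1/2)`; under the multiplicative random-effects
#' (MRE) model the SE is scaled by `sqrt(phi)` with overdispersion
#' `phi = Q/(J-1)` (not truncated at 1), where `Q` is Cochran's statistic of
#' the residuals. With a single SNP the estimate reduces to the Wald ratio.
#'
#' @param set a [harmonized_set()].
#' @param mode `"mre"` (default, the primary analysis model) or `"fixed"`.
#' @return An [mr_estimate()] with extras `cochran_q`, `q_pvalue`, `phi`.
#' @export
mr_ivw <- function(set, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  j <- n_snps(set)
  if (j < 1) stopf("ivw needs at least 1 SNP")
  gx <- set$snps$beta_exposure
  gy <- set$snps$beta_outcome
  if (all(gx == 0)) stopf("ivw undefined: all exposure effects are zero")
  if (j == 1) {
    return(mr_wald_ratio(gx, set$snps$se_exposure, gy, set$snps$se_outcome))
  }
  w <- set_weights(set)
  theta <- sum(w * gx * gy) / sum(w * gx^2)
  se_fixed <- 1 / sqrt(sum(w * gx^2))
  q <- sum(w * (gy - theta * gx)^2)
  phi <- q / (j - 1)
  se <- if (mode == "mre") se_fixed * sqrt(phi) else se_fixed
  mr_estimate(paste0("ivw_", if (mode == "mre") "mre" else "fe"),
              theta, se, n_snps = j,
              extras = list(cochran_q = q,
                            q_pvalue = stats::pchisq(q, df = j - 1, lower.tail = FALSE),
                            phi = phi, se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept, after orienting every SNP so its exposure effect
#' is non-negative. The intercept estimates the average directional
#' pleiotropy; its test is the standard check for unbalanced horizontal
#' pleiotropy. Multiplicative overdispersion `phi = RSS/(J-2)`, floored at 1,
#' scales both standard errors; inference uses the t distribution with `J - 2`
#' degrees of freedom.
#'
#' @param set a [harmonized_set()] with at least 3 SNPs.
#' @return An [mr_estimate()] with extras `egger_intercept`, `intercept_se`,
#'   `intercept_p`, `phi`, `cochran_q` (RSS on the weighted scale).
#' @export
mr_egger <- function(set) {
  j <- n_snps(set)
  if (j < 3) stopf("MR-Egger needs at least 3 SNPs")
  flip <- sign(set$snps$beta_exposure)
  flip[flip == 0] <- 1
  gx <- set$snps$beta_exposure * flip
  gy <- set$snps$beta_outcome * flip
  w <- set_weights(set)

  sw <- sum(w); swx <- sum(w * gx); swy <- sum(w * gy)
  swxy <- sum(w * gx * gy); swx2 <- sum(w * gx^2)
  denom <- sw * swx2 - swx^2
  if (denom <= 0) stopf("MR-Egger: degenerate design (no spread in exposure effects)")
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swy - slope * swx) / sw
  rss <- sum(w * (gy - intercept - slope * gx)^2)
  phi <- max(1, rss / (j - 2))
  se_slope <- sqrt(sw / denom * phi)
  se_int <- sqrt(swx2 / denom * phi)

  est <- mr_estimate("egger", slope, se_slope, n_snps = j, df = j - 2,
                     extras = list(egger_intercept = intercept,
                                   intercept_se = se_int,
                                   intercept_p = p_from_t(intercept / se_int, j - 2),
                                   phi = phi, cochran_q = rss))
  est
}

# Interpolated weighted median of ratio estimates.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

ratio_estimates <- function(set) {
  gx <- set$snps$beta_exposure
  if (any(gx == 0)) stopf("ratio estimates undefined: zero exposure effect")
  list(theta = set$snps$beta_outcome / gx,
       w = (gx / set$snps$se_outcome)^2)  # first-order inverse variance
}

parametric_bootstrap_se <- function(set, point_fun, reps, seed) {
  gx <- set$snps$beta_exposure; sx <- set$snps$se_exposure
  gy <- set$snps$beta_outcome; sy <- set$snps$se_outcome
  j <- length(gx)
  with_seed(seed, {
    est <- vapply(seq_len(reps), function(i) {
      gxs <- stats::rnorm(j, gx, sx)
      gys <- stats::rnorm(j, gy, sy)
      gxs[gxs == 0] <- .Machine$double.eps
      point_fun(gys / gxs, (gxs / sy)^2)
    }, 0)
    stats::sd(est)
  })
}

#' Weighted median estimate
#'
#' Median of the per-SNP ratio estimates under inverse-variance weights
#' (first-order), computed by linear interpolation of the sorted ratios
#' against centred normalized cumulative weights. Consistent when instruments
#' carrying more than half the weight are valid. The SE comes from a seeded
#' parametric bootstrap resampling the summary effects from normal
#' distributions with their reported SEs.
#'
#' @param set a [harmonized_set()] with at least 3 SNPs.
#' @param bootstrap_reps bootstrap replications for the SE; `0` returns the
#'   point estimate with `NA` SE.
#' @param seed bootstrap seed (required when `bootstrap_reps > 0`).
#' @return An [mr_estimate()] with extras `bootstrap_reps`, `seed`.
#' @export
mr_weighted_median <- function(set, bootstrap_reps = 1000, seed = NULL) {
  if (n_snps(set) < 3) stopf("weighted median needs at least 3 SNPs")
  r <- ratio_estimates(set)
  theta <- weighted_median_point(r$theta, r$w)
  se <- NA_real_
  if (bootstrap_reps > 0) {
    if (is.null(seed)) stopf("weighted median bootstrap requires a seed")
    se <- parametric_bootstrap_se(set, weighted_median_point, bootstrap_reps, seed)
  }
  mr_estimate("weighted_median", theta, se, n_snps = n_snps(set),
              extras = list(bootstrap_reps = bootstrap_reps, seed = seed))
}

# Argmax of the weighted Gaussian kernel density of the ratio estimates.
# Bandwidth follows the modified Silverman rule; ties break toward the
# smaller theta (ascending grid, first maximum).
weighted_mode_point <- function(theta, w, bandwidth_factor = 1) {
  if (length(unique(theta)) == 1) return(theta[1])
  s <- stats::sd(theta)
  m <- stats::mad(theta)  # default constant 1.4826 = 1/0.6745
  base <- if (m > 0) min(s, m) else s
  h <- bandwidth_factor * 0.9 * base * length(theta)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(theta[which.max(w)])
  lo <- min(theta) - 3 * h
  hi <- max(theta) + 3 * h
  grid <- seq(lo, hi, length.out = max(512L, ceiling((hi - lo) / (h / 10)) + 1L))
  dens <- colSums(w * stats::dnorm(outer(theta, grid, "-") / h)) # common 1/h factor dropped
  grid[which.max(dens)]
}

#' Weighted mode estimate
#'
#' Mode of the weighted kernel density of the per-SNP ratio estimates:
#' consistent when the largest group of instruments sharing a ratio value is
#' valid, even if they are a minority by count. Bandwidth is
#' `bandwidth_factor * 0.9 * min(sd, mad) * J^(-1/5)` (the mad term skipped
#' when zero); the density is maximized on a grid spanning the ratios padded
#' by `3h` at resolution at most `h/10`. SE by seeded parametric bootstrap.
#'
#' @param set a [harmonized_set()] with at least 3 SNPs.
#' @param bandwidth_factor kernel bandwidth multiplier (1 = NOME default).
#' @param bootstrap_reps,seed as in [mr_weighted_median()].
#' @return An [mr_estimate()] with extras `bandwidth_factor`,
#'   `bootstrap_reps`, `seed`.
#' @export
mr_weighted_mode <- function(set, bandwidth_factor = 1, bootstrap_reps = 1000,
                             seed = NULL) {
  if (n_snps(set) < 3) stopf("weighted mode needs at least 3 SNPs")
  r <- ratio_estimates(set)
  theta <- weighted_mode_point(r$theta, r$w, bandwidth_factor)
  se <- NA_real_
  if (bootstrap_reps > 0) {
    if (is.null(seed)) stopf("weighted mode bootstrap requires a seed")
    se <- parametric_bootstrap_se(
      set, function(th, w) weighted_mode_point(th, w, bandwidth_factor),
      bootstrap_reps, seed)
  }
  mr_estimate("weighted_mode", theta, se, n_snps = n_snps(set),
              extras = list(bandwidth_factor = bandwidth_factor,
                            bootstrap_reps = bootstrap_reps, seed = seed))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (beta_outcome_j - theta * beta_exposure_j)^2` with weights
#' `1/se_outcome^2`, compared to a chi-square distribution with `J -
#' df_reduction` degrees of freedom (`df_reduction = 1` for IVW residuals,
#' `2` for Egger residuals).
#'
#' @param set a [harmonized_set()].
#' @param theta causal estimate defining the residuals.
#' @param df_reduction parameters absorbed by the fit.
#' @return list with `q`, `df`, `pvalue`.
#' @export
mr_cochran_q <- function(set, theta, df_reduction = 1) {
  if (!is.finite(theta)) stopf("theta must be finite")
  w <- set_weights(set)
  q <- sum(w * (set$snps$beta_outcome - theta * set$snps$beta_exposure)^2)
  df <- n_snps(set) - df_reduction
  list(q = q, df = df,
       pvalue = if (df > 0) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_)
}

#' Run the standard estimator battery
#'
#' IVW (multiplicative random effects), MR-Egger, weighted median and
#' weighted mode on one harmonized set, with bootstrap seeds derived from a
#' single master seed.
#'
#' @param set a [harmonized_set()].
#' @param bootstrap_reps bootstrap replications for median/mode SEs.
#' @param seed master seed for all randomness.
#' @return Named list of [mr_estimate()] objects.
#' @export
mr_all <- function(set, bootstrap_reps = 1000, seed = 1) {
  list(
    ivw_mre = mr_ivw(set, mode = "mre"),
    egger = mr_egger(set),
    weighted_median = mr_weighted_median(set, bootstrap_reps,
                                         seed = derive_seed(seed, 1)),
    weighted_mode = mr_weighted_mode(set, bootstrap_reps = bootstrap_reps,
                                     seed = derive_seed(seed, 2))
  )
}

#' Flatten MR estimates into a results table
#'
#' One row per method with the effect on both the log-odds and odds-ratio
#' scales, mirroring the layout of a forest table.
#'
#' @param estimates named list of [mr_estimate()] objects.
#' @return data frame.
#' @export
estimates_table <- function(estimates) {
  rows <- lapply(estimates, function(e) {
    data.frame(method = e$method, n_snps = e$n_snps, theta = e$theta,
               se = e$se, or = exp(e$theta),
               or_ci_low = exp(e$ci_low), or_ci_high = exp(e$ci_high),
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize MR estimates to JSON
#'
#' @param estimates named list of [mr_estimate()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
estimates_json <- function(estimates, path) {
  payload <- lapply(estimates, function(e) {
    list(method = e$method, theta = e$theta, or = exp(e$theta), se = e$se,
         ci_low = e$ci_low, ci_high = e$ci_high,
         or_ci_low = exp(e$ci_low), or_ci_high = exp(e$ci_high),
         pvalue = e$pvalue, n_snps = e$n_snps, extras = e$extras)
  })
  write_json_report(payload, path)
}
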