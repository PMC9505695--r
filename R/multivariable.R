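# Multivariable MR and two-step MR mediation.

#' Multivariable IVW regression
#'
#' Weighted least squares of SNP-outcome effects on the J x K matrix of
#' SNP-exposure effects with weights `1/se_outcome^2` and no intercept,
#' estimating each exposure's direct effect conditional on the others.
#' Multiplicative overdispersion `phi = RSS/(J - K)`, floored at 1, scales the
#' standard errors; p-values are normal.
#'
#' @param bx J x K numeric matrix of exposure effects (one column per
#'   exposure).
#' @param by length-J vector of outcome effects.
#' @param se_outcome length-J vector of outcome SEs.
#' @param exposure_ids exposure labels; defaults to `colnames(bx)`.
#' @return Object of class `mvmr_estimate`: list with `exposure_ids`,
#'   `theta`, `se`, `pvalue`, `cov` (K x K covariance of the estimates),
#'   `phi`, `n_snps`.
#' @export
mvmr_ivw <- function(bx, by, se_outcome, exposure_ids = colnames(bx)) {
  bx <- as.matrix(bx)
  j <- nrow(bx); k <- ncol(bx)
  if (is.null(exposure_ids)) exposure_ids <- paste0("exposure_", seq_len(k))
  if (length(by) != j || length(se_outcome) != j) {
    stopf("bx, by and se_outcome must cover the same %d SNPs", j)
  }
  if (j <= k) stopf("multivariable IVW needs more SNPs (%d) than exposures (%d)", j, k)
  if (any(se_outcome <= 0)) stopf("se_outcome must be positive")
  w <- 1 / se_outcome^2
  xtwx <- crossprod(bx, bx * w)
  qr_x <- qr(xtwx)
  if (qr_x$rank < k) {
    dep <- exposure_ids[qr_x$pivot[seq(qr_x$rank + 1, k)]]
    stopf("collinear exposure effects: %s", paste(dep, collapse = ", "))
  }
  xtwy <- crossprod(bx, by * w)
  theta <- drop(solve(xtwx, xtwy))
  resid <- by - drop(bx %*% theta)
  rss <- sum(w * resid^2)
  phi <- max(1, rss / (j - k))
  cov_theta <- solve(xtwx) * phi
  se <- sqrt(diag(cov_theta))
  structure(list(exposure_ids = exposure_ids,
                 theta = stats::setNames(theta, exposure_ids),
                 se = stats::setNames(se, exposure_ids),
                 pvalue = stats::setNames(p_from_z(theta / se), exposure_ids),
                 cov = cov_theta, phi = phi, rss = rss, n_snps = j),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("Multivariable IVW on %d SNPs (phi = %.3f)\n", x$n_snps, x$phi))
  for (id in x$exposure_ids) {
    cat(sprintf("  %s: theta = %.4f (se %.4f), p = %.3g\n",
                id, x$theta[id], x$se[id], x$pvalue[id]))
  }
  invisible(x)
}

#' Build a multivariable MR design from summary tables
#'
#' Aligns each exposure's and the outcome's summary statistics onto the
#' allele orientation of the first exposure, restricted to the supplied
#' variant panel (default: variants present in every dataset).
#'
#' @param exposures named list of summary-statistic data frames.
#' @param outcome summary-statistic data frame.
#' @param variant_ids optional panel restriction.
#' @return list with `bx`, `se_bx` (J x K matrices), `by`, `se_by`,
#'   `variant_ids`, `exposure_ids`.
#' @export
harmonize_mvmr <- function(exposures, outcome, variant_ids = NULL) {
  stopifnot(length(exposures) >= 1)
  ids <- names(exposures) %||% paste0("exposure_", seq_along(exposures))
  ref <- exposures[[1]]
  panel <- ref$variant_id
  for (e in exposures[-1]) panel <- intersect(panel, e$variant_id)
  panel <- intersect(panel, outcome$variant_id)
  if (!is.null(variant_ids)) panel <- intersect(panel, variant_ids)
  if (length(panel) == 0) stopf("no variants shared by all datasets")

  aligned <- lapply(seq_along(exposures), function(i) {
    h <- harmonize(ref, exposures[[i]], palindrome_policy = "keep")
    s <- h$snps[match(panel, h$snps$variant_id), , drop = FALSE]
    if (anyNA(s$variant_id)) stopf("exposure '%s' lost panel variants in harmonization", ids[i])
    s
  })
  hy <- harmonize(ref, outcome, palindrome_policy = "keep")
  sy <- hy$snps[match(panel, hy$snps$variant_id), , drop = FALSE]
  if (anyNA(sy$variant_id)) stopf("outcome lost panel variants in harmonization")

  bx <- do.call(cbind, lapply(aligned, function(s) s$beta_outcome))
  se_bx <- do.call(cbind, lapply(aligned, function(s) s$se_outcome))
  colnames(bx) <- colnames(se_bx) <- ids
  list(bx = bx, se_bx = se_bx, by = sy$beta_outcome, se_by = sy$se_outcome,
       variant_ids = panel, exposure_ids = ids)
}

#' Two-step MR mediation by the product method
#'
#' Combines the exposure-to-mediator effect (`beta1`) and the
#' exposure-adjusted mediator-to-outcome effect (`beta2`) into the indirect
#' (mediation) effect `beta1 * beta2`, with a seeded parametric bootstrap
#' percentile interval on the odds-ratio scale (independent normal draws for
#' the two stages) and the proportion mediated `indirect / total_effect`.
#'
#' @param beta1,se1 stage-1 estimate and SE (exposure -> mediator).
#' @param beta2,se2 stage-2 estimate and SE (mediator -> outcome, adjusted).
#' @param total_effect total exposure -> outcome effect (log-odds); the
#'   proportion mediated is flagged as undefined when it is zero.
#' @param bootstrap_reps bootstrap draws.
#' @param seed RNG seed.
#' @return Object of class `mediation_result`.
#' @export
mediate_two_step <- function(beta1, se1, beta2, se2, total_effect,
                             bootstrap_reps = 10000, seed = 1) {
  if (se1 <= 0 || se2 <= 0) stopf("stage SEs must be positive")
  indirect <- beta1 * beta2
  ci <- with_seed(seed, {
    b1 <- stats::rnorm(bootstrap_reps, beta1, se1)
    b2 <- stats::rnorm(bootstrap_reps, beta2, se2)
    stats::quantile(exp(b1 * b2), c(0.025, 0.975), names = FALSE, type = 7)
  })
  proportion <- if (total_effect == 0) NA_real_ else indirect / total_effect
  structure(list(beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 indirect = indirect, indirect_or = exp(indirect),
                 ci_low = ci[1], ci_high = ci[2],
                 total_effect = total_effect,
                 proportion_mediated = proportion,
                 proportion_defined = total_effect != 0,
                 bootstrap_reps = bootstrap_reps, seed = seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Two-step MR mediation\n  beta1 = %.4f (se %.4f), beta2 = %.4f (se %.4f)\n",
              x$beta1, x$se1, x$beta2, x$se2))
  cat(sprintf("  indirect = %.4f, OR = %.3f [%.3f, %.3f]\n",
              x$indirect, x$indirect_or, x$ci_low, x$ci_high))
  if (x$proportion_defined) {
    cat(sprintf("  proportion mediated = %.3g%% of total %.4f\n",
                100 * x$proportion_mediated, x$total_effect))
  } else {
    cat("  proportion mediated undefined (total effect is zero)\n")
  }
  invisible(x)
}

#' Full two-step mediation pipeline on summary data
#'
#' Stage 1 estimates the exposure-to-mediator effect by univariable IVW on
#' the exposure's instruments. Stage 2 estimates the mediator-to-outcome
#' effect adjusted for the exposure by multivariable IVW on the union of both
#' traits' instruments, optionally excluding MR-PRESSO outliers of the
#' univariable mediator-to-outcome analysis first. The total effect is the
#' univariable IVW of the outcome on the exposure's instruments; the pieces
#' are combined by [mediate_two_step()].
#'
#' @param exposure,mediator,outcome summary-statistic data frames covering a
#'   common variant panel.
#' @param p_threshold instrument-selection p-value threshold.
#' @param maf_min minor-allele-frequency floor for instrument selection.
#' @param presso_exclude run MR-PRESSO on the univariable mediator-outcome
#'   set and drop flagged outliers before stage 2.
#' @param presso_sims MR-PRESSO simulation count.
#' @param bootstrap_reps mediation bootstrap draws.
#' @param seed master seed.
#' @return A `mediation_result` with an `extras` attribute carrying the stage
#'   estimates, instrument counts and excluded outliers.
#' @export
mediation_pipeline <- function(exposure, mediator, outcome,
                               p_threshold = 5e-8, maf_min = 0.01,
                               presso_exclude = TRUE, presso_sims = 1000,
                               bootstrap_reps = 10000, seed = 1) {
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stopf("mediation stage '%s' failed: %s", label, conditionMessage(e))
    })
  }
  exp_ins <- stage("exposure instrument selection",
                   filter_instruments(exposure, p_threshold, maf_min)$records)
  med_ins <- stage("mediator instrument selection",
                   filter_instruments(mediator, p_threshold, maf_min)$records)

  stage1 <- stage("stage 1 (exposure -> mediator)",
                  mr_ivw(harmonize(exp_ins, mediator), mode = "mre"))
  total <- stage("total effect (exposure -> outcome)",
                 mr_ivw(harmonize(exp_ins, outcome), mode = "mre"))

  outlier_ids <- character(0)
  if (presso_exclude) {
    uni_my <- stage("mediator -> outcome univariable set",
                    harmonize(med_ins, outcome))
    pres <- stage("MR-PRESSO outlier screen",
                  mr_presso(uni_my, n_simulations = presso_sims,
                            seed = derive_seed(seed, 31)))
    outlier_ids <- pres$outlier_ids
  }

  panel_records <- rbind(med_ins, exp_ins[!exp_ins$variant_id %in% med_ins$variant_id, ])
  panel_records <- panel_records[!panel_records$variant_id %in% outlier_ids, ]
  design <- stage("stage 2 design", harmonize_mvmr(
    exposures = list(mediator = mediator, exposure = exposure),
    outcome = outcome, variant_ids = panel_records$variant_id))
  stage2 <- stage("stage 2 (mediator -> outcome | exposure)",
                  mvmr_ivw(design$bx, design$by, design$se_by,
                           exposure_ids = design$exposure_ids))

  res <- mediate_two_step(stage1$theta, stage1$se,
                          stage2$theta[["mediator"]], stage2$se[["mediator"]],
                          total_effect = total$theta,
                          bootstrap_reps = bootstrap_reps,
                          seed = derive_seed(seed, 32))
  attr(res, "extras") <- list(stage1 = stage1, stage2 = stage2, total = total,
                              n_exposure_instruments = nrow(exp_ins),
                              n_mediator_instruments = nrow(med_ins),
                              excluded_outliers = outlier_ids,
                              n_panel = length(design$variant_ids))
  res
}

#' Serialize a mediation result to JSON
#'
#' @param x a `mediation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
mediation_json <- function(x, path) {
  payload <- list(beta1 = x$beta1, se1 = x$se1, beta2 = x$beta2, se2 = x$se2,
                  indirect = x$indirect, indirect_or = x$indirect_or,
                  or_ci_low = x$ci_low, or_ci_high = x$ci_high,
                  total_effect = x$total_effect,
                  proportion_mediated = x$proportion_mediated,
                  bootstrap_reps = x$bootstrap_reps, seed = x$seed)
  write_json_report(payload, path)
}
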