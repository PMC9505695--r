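# Synthetic two-sample GWAS summary statistics with known ground truth.
#
# The generator works entirely at the summary level: true per-SNP effects are
# drawn first, then the reported estimates are the truth plus normal noise at
# the analytic standard errors implied by sample size and allele frequency.

NON_PALINDROMIC_PAIRS <- matrix(c("A","G", "A","C", "T","G", "T","C",
                                  "G","A", "C","A", "G","T", "C","T"),
                                ncol = 2, byrow = TRUE)

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a large vitamin-D-style
#' exposure GWAS and a migraine-style case-control outcome GWAS: 184
#' independent instruments explaining 4% of a rank-normalized variance-1
#' exposure measured in 417,580 individuals, per-SNP F statistics drawn as
#' `30 + Exponential(mean 60)` (floor at the genome-wide-significance edge,
#' mean near 92), and an outcome of 589,356 individuals at case fraction
#' 0.0831 with a true causal log-odds effect of `log(0.916)` per SD exposure.
#'
#' @param n_snps number of instruments (>= 3).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param case_fraction outcome case fraction (binary outcome).
#' @param theta true causal log-odds per SD exposure.
#' @param pve total proportion of exposure variance explained by the forward
#'   instruments.
#' @param maf_range range of minor allele frequencies.
#' @param f_min,f_scale per-SNP F statistics are drawn as
#'   `f_min + Exponential(mean f_scale)` before the PVE rescaling.
#' @param gamma_sign `"random"` (effect alleles in arbitrary orientation, as
#'   in real summary files) or `"positive"` (all oriented
#'   exposure-increasing, convenient for pleiotropy simulations).
#' @param mu_alpha,sigma_alpha mean and SD of the pleiotropic outcome effects
#'   of invalid instruments.
#' @param rho_inside correlation between pleiotropic effects and instrument
#'   strength (an InSIDE violation when nonzero).
#' @param frac_invalid fraction of forward instruments given pleiotropic
#'   effects.
#' @param n_outliers number of planted gross pleiotropic outliers.
#' @param outlier_scale outlier offset in units of the outcome SE.
#' @param n_reverse number of planted reverse-causal (outcome-first) SNPs.
#' @param reverse_beta outcome-to-exposure scaling of reverse SNPs.
#' @param reverse_f target outcome-side F statistic of reverse SNPs.
#' @param flip_fraction fraction of outcome records emitted with swapped
#'   alleles (exercises harmonization; corrected exactly downstream).
#' @param seed mandatory RNG seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 184, n_exposure = 417580, n_outcome = 589356,
                       case_fraction = 0.0831, theta = log(0.916), pve = 0.04,
                       maf_range = c(0.05, 0.5), f_min = 30, f_scale = 60,
                       gamma_sign = c("random", "positive"),
                       mu_alpha = 0, sigma_alpha = 0, rho_inside = 0,
                       frac_invalid = 0, n_outliers = 0, outlier_scale = 10,
                       n_reverse = 0, reverse_beta = 0.2, reverse_f = 90,
                       flip_fraction = 0.2, seed) {
  if (missing(seed)) stopf("sim_config: seed is mandatory")
  gamma_sign <- match.arg(gamma_sign)
  cfg <- list(n_snps = n_snps, n_exposure = n_exposure, n_outcome = n_outcome,
              case_fraction = case_fraction, theta = theta, pve = pve,
              maf_range = maf_range, f_min = f_min, f_scale = f_scale,
              gamma_sign = gamma_sign, mu_alpha = mu_alpha,
              sigma_alpha = sigma_alpha, rho_inside = rho_inside,
              frac_invalid = frac_invalid, n_outliers = n_outliers,
              outlier_scale = outlier_scale, n_reverse = n_reverse,
              reverse_beta = reverse_beta, reverse_f = reverse_f,
              flip_fraction = flip_fraction, seed = as.integer(seed))
  if (n_snps < 3) stopf("n_snps must be at least 3")
  if (pve <= 0 || pve >= 1) stopf("infeasible PVE target: %g", pve)
  for (f in c("case_fraction", "frac_invalid", "flip_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("%s must lie in [0,1]", f)
  }
  if (abs(rho_inside) > 1) stopf("rho_inside must lie in [-1,1]")
  if (n_reverse + 3 > n_snps) stopf("too many reverse-causal SNPs for n_snps")
  structure(cfg, class = "sim_config")
}

sim_alleles <- function(j) {
  pick <- sample.int(nrow(NON_PALINDROMIC_PAIRS), j, replace = TRUE)
  list(ea = NON_PALINDROMIC_PAIRS[pick, 1], oa = NON_PALINDROMIC_PAIRS[pick, 2])
}

sim_records <- function(id, chrom, pos, ea, oa, eaf, beta_hat, se, n,
                        n_cases, trait_id) {
  data.frame(variant_id = id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta_hat, se = se,
             pvalue = pmax(p_from_z(beta_hat / se), .Machine$double.xmin),
             n = n, n_cases = n_cases, trait_id = trait_id,
             stringsAsFactors = FALSE)
}

# Swap effect/other alleles of selected rows, negating beta and flipping eaf.
swap_alleles <- function(records, idx) {
  ea <- records$effect_allele[idx]
  records$effect_allele[idx] <- records$other_allele[idx]
  records$other_allele[idx] <- ea
  records$beta[idx] <- -records$beta[idx]
  records$eaf[idx] <- 1 - records$eaf[idx]
  records
}

#' Simulate a two-sample MR dataset
#'
#' Draws minor allele frequencies, true instrument effects scaled so the
#' forward instruments jointly explain the target PVE of a variance-1
#' exposure, pleiotropic effects under the configured regime, planted
#' outliers and reverse-causal SNPs, then emits noisy summary statistics for
#' both traits. The exposure SE per SNP is `(2 maf (1-maf) n)^(-1/2)`; the
#' binary outcome uses the case-control analogue with the extra
#' `phi (1 - phi)` factor on the log-odds scale. A `truth` record stores
#' every latent quantity, so estimator bias and coverage can be computed
#' exactly.
#'
#' @param config a [sim_config()].
#' @return list of class `mr_simulation` with `exposure`, `outcome` (summary
#'   data frames that pass [validate_summary()]) and `truth`.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    j <- config$n_snps
    maf <- stats::runif(j, config$maf_range[1], config$maf_range[2])
    het <- 2 * maf * (1 - maf)
    sigma_x <- 1 / sqrt(het * config$n_exposure)
    phi <- config$case_fraction
    sigma_y <- 1 / sqrt(het * config$n_outcome * phi * (1 - phi))

    reverse_idx <- if (config$n_reverse > 0) sort(sample.int(j, config$n_reverse)) else integer(0)
    fwd <- setdiff(seq_len(j), reverse_idx)

    # forward instrument effects: F floor + exponential tail, rescaled to the
    # PVE target
    f_draw <- config$f_min + stats::rexp(length(fwd), rate = 1 / config$f_scale)
    sgn <- if (config$gamma_sign == "positive") rep(1, length(fwd))
           else sample(c(-1, 1), length(fwd), replace = TRUE)
    gamma <- numeric(j)
    gamma[fwd] <- sgn * sqrt(f_draw) * sigma_x[fwd]
    pve_raw <- sum(2 * gamma[fwd]^2 * maf[fwd] * (1 - maf[fwd]))
    gamma[fwd] <- gamma[fwd] * sqrt(config$pve / pve_raw)

    # reverse-causal SNPs act on the outcome first
    delta <- numeric(j)
    if (length(reverse_idx) > 0) {
      dsgn <- sample(c(-1, 1), length(reverse_idx), replace = TRUE)
      delta[reverse_idx] <- dsgn * sqrt(config$reverse_f) * sigma_y[reverse_idx]
      gamma[reverse_idx] <- config$reverse_beta * delta[reverse_idx]
    }

    # pleiotropy, optionally correlated with instrument strength
    alpha <- numeric(j)
    invalid_idx <- integer(0)
    n_invalid <- round(config$frac_invalid * length(fwd))
    if (n_invalid > 0 && (config$sigma_alpha > 0 || config$mu_alpha != 0)) {
      invalid_idx <- sort(sample(fwd, n_invalid))
      zg <- gamma[invalid_idx]
      zg <- if (stats::sd(zg) > 0) (zg - mean(zg)) / stats::sd(zg) else rep(0, n_invalid)
      z <- stats::rnorm(n_invalid)
      alpha[invalid_idx] <- config$mu_alpha + config$sigma_alpha *
        (config$rho_inside * zg + sqrt(1 - config$rho_inside^2) * z)
    }

    gamma_big <- numeric(j)
    gamma_big[fwd] <- config$theta * gamma[fwd] + alpha[fwd]
    gamma_big[reverse_idx] <- delta[reverse_idx]

    outlier_idx <- integer(0)
    if (config$n_outliers > 0) {
      pool <- setdiff(fwd, invalid_idx)
      if (length(pool) < config$n_outliers) pool <- fwd
      outlier_idx <- sort(sample(pool, config$n_outliers))
      gamma_big[outlier_idx] <- gamma_big[outlier_idx] +
        config$outlier_scale * sigma_y[outlier_idx]
    }

    beta_x_hat <- stats::rnorm(j, gamma, sigma_x)
    beta_y_hat <- stats::rnorm(j, gamma_big, sigma_y)

    al <- sim_alleles(j)
    eaf_side <- stats::runif(j) < 0.5
    eaf <- ifelse(eaf_side, maf, 1 - maf)
    chroms <- as.character(c(1:5, 7:22))  # avoid the HLA chromosome
    chrom <- rep_len(chroms, j)
    pos <- 1e6 * seq_len(j)
    ids <- sprintf("snp%05d", seq_len(j))

    exposure <- sim_records(ids, chrom, pos, al$ea, al$oa, eaf,
                            beta_x_hat, sigma_x, config$n_exposure,
                            NA_real_, "exposure_sim")
    outcome <- sim_records(ids, chrom, pos, al$ea, al$oa, eaf,
                           beta_y_hat, sigma_y, config$n_outcome,
                           round(phi * config$n_outcome), "outcome_sim")
    n_flip <- round(config$flip_fraction * j)
    if (n_flip > 0) {
      outcome <- swap_alleles(outcome, sort(sample.int(j, n_flip)))
    }

    truth <- list(gamma = gamma, alpha = alpha, delta = delta,
                  gamma_outcome = gamma_big, maf = maf,
                  sigma_x = sigma_x, sigma_y = sigma_y,
                  theta = config$theta, pve_target = config$pve,
                  invalid_idx = invalid_idx, outlier_idx = outlier_idx,
                  reverse_idx = reverse_idx,
                  outlier_ids = ids[outlier_idx],
                  reverse_ids = ids[reverse_idx],
                  invalid_ids = ids[invalid_idx],
                  seed = config$seed)
    structure(list(exposure = exposure, outcome = outcome, truth = truth,
                   config = config),
              class = "mr_simulation")
  })
}

#' Simulate a mediation chain
#'
#' Builds three GWAS summary tables over one SNP panel: exposure instruments
#' act on the mediator through `beta_xm` and on the outcome through the
#' direct path plus the mediated path `beta_xm * beta_my`; mediator-specific
#' instruments act on the mediator directly and on the outcome through
#' `beta_my` only. Defaults calibrate the chain to a vitamin-D -> serum
#' calcium -> migraine structure (stage effects 0.0504 and 0.0601, direct
#' path -0.0908, hence total -0.0878).
#'
#' @param config_x exposure [sim_config()] (its `theta` is ignored; use
#'   `theta_direct`).
#' @param config_m mediator [sim_config()]; `n_snps` counts the
#'   mediator-specific instruments and `n_exposure` is the mediator GWAS
#'   sample size (the mediator is a variance-1 quantitative trait).
#' @param config_y list with `n` and `case_fraction` for the outcome GWAS.
#' @param beta_xm exposure -> mediator effect.
#' @param beta_my mediator -> outcome effect (log-odds per mediator SD).
#' @param theta_direct direct exposure -> outcome effect (log-odds).
#' @param seed master seed; the default stage configs derive theirs from it.
#' @return list of class `mediation_simulation` with `exposure`, `mediator`,
#'   `outcome` summary tables and `truth`.
#' @export
simulate_mediation_chain <- function(config_x = sim_config(seed = seed),
                                     config_m = sim_config(
                                       n_snps = 210, n_exposure = 300000,
                                       pve = 0.02, seed = seed + 1),
                                     config_y = list(n = 750000,
                                                     case_fraction = 68597 / 750000),
                                     beta_xm = 0.0504, beta_my = 0.0601,
                                     theta_direct = -0.0908, seed = 1) {
  stopifnot(inherits(config_x, "sim_config"), inherits(config_m, "sim_config"))
  with_seed(derive_seed(seed, 7), {
    jx <- config_x$n_snps; jm <- config_m$n_snps
    j <- jx + jm
    is_x <- seq_len(jx)
    is_m <- jx + seq_len(jm)

    maf <- stats::runif(j, min(config_x$maf_range[1], config_m$maf_range[1]),
                        max(config_x$maf_range[2], config_m$maf_range[2]))
    het <- 2 * maf * (1 - maf)
    sigma_x <- 1 / sqrt(het * config_x$n_exposure)
    sigma_m <- 1 / sqrt(het * config_m$n_exposure)
    phi <- config_y$case_fraction
    sigma_y <- 1 / sqrt(het * config_y$n * phi * (1 - phi))

    draw_gamma <- function(idx, cfg) {
      f <- cfg$f_min + stats::rexp(length(idx), rate = 1 / cfg$f_scale)
      g <- sqrt(f) / sqrt(het[idx] * cfg$n_exposure)
      g * sqrt(cfg$pve / sum(2 * g^2 * maf[idx] * (1 - maf[idx])))
    }
    gamma_x <- numeric(j); gamma_x[is_x] <- draw_gamma(is_x, config_x)
    gamma_m_own <- numeric(j); gamma_m_own[is_m] <- draw_gamma(is_m, config_m)

    # true effects on each trait
    eff_x <- gamma_x
    eff_m <- beta_xm * gamma_x + gamma_m_own
    eff_y <- theta_direct * gamma_x + beta_my * eff_m

    bx <- stats::rnorm(j, eff_x, sigma_x)
    bm <- stats::rnorm(j, eff_m, sigma_m)
    by <- stats::rnorm(j, eff_y, sigma_y)

    al <- sim_alleles(j)
    eaf <- ifelse(stats::runif(j) < 0.5, maf, 1 - maf)
    chrom <- rep_len(as.character(c(1:5, 7:22)), j)
    pos <- 1e6 * seq_len(j)
    ids <- sprintf("snp%05d", seq_len(j))

    truth <- list(beta_xm = beta_xm, beta_my = beta_my,
                  theta_direct = theta_direct,
                  indirect = beta_xm * beta_my,
                  total = theta_direct + beta_xm * beta_my,
                  gamma_x = gamma_x, gamma_m = gamma_m_own,
                  exposure_snp_ids = ids[is_x], mediator_snp_ids = ids[is_m],
                  seed = seed)
    structure(list(
      exposure = sim_records(ids, chrom, pos, al$ea, al$oa, eaf, bx, sigma_x,
                             config_x$n_exposure, NA_real_, "exposure_sim"),
      mediator = sim_records(ids, chrom, pos, al$ea, al$oa, eaf, bm, sigma_m,
                             config_m$n_exposure, NA_real_, "mediator_sim"),
      outcome = sim_records(ids, chrom, pos, al$ea, al$oa, eaf, by, sigma_y,
                            config_y$n, round(phi * config_y$n), "outcome_sim"),
      truth = truth), class = "mediation_simulation")
  })
}

#' Simulate a block-diagonal LD matrix
#'
#' Squared correlations equal to `within_r2` inside consecutive blocks of
#' `block_size` variants and zero between blocks, with unit diagonal.
#' Variant ids follow the `snp%05d` convention of [simulate_two_sample()].
#'
#' @param n_snps number of variants.
#' @param block_size variants per block (the final block may be shorter).
#' @param within_r2 within-block squared correlation in `[0, 1]`.
#' @param seed unused draw-wise (the structure is deterministic) but kept for
#'   interface symmetry.
#' @return Validated LD matrix.
#' @export
simulate_ld_blocks <- function(n_snps, block_size, within_r2, seed = 1) {
  if (within_r2 < 0 || within_r2 > 1) stopf("within_r2 must lie in [0,1]")
  block <- rep(seq_len(ceiling(n_snps / block_size)), each = block_size)[seq_len(n_snps)]
  r2 <- outer(block, block, function(a, b) ifelse(a == b, within_r2, 0))
  diag(r2) <- 1
  ids <- sprintf("snp%05d", seq_len(n_snps))
  dimnames(r2) <- list(ids, ids)
  validate_ld_matrix(r2)
  r2
}

#' Write a simulation to disk
#'
#' Emits the summary tables in the standard TSV dialect plus the truth record
#' as JSON beside them. Byte-identical across runs for a fixed config.
#'
#' @param sim an `mr_simulation` or `mediation_simulation`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- sim[vapply(sim, is.data.frame, TRUE)]
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, nm))
    write_summary(tables[[nm]], p)
    paths[nm] <- p
  }
  tp <- file.path(dir, sprintf("%s_truth.json", prefix))
  write_json_report(sim$truth, tp)
  paths["truth"] <- tp
  invisible(paths)
}
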