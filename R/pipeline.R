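# Configuration-driven orchestration of the full analysis and reporting.

#' Analysis configuration
#'
#' Assembles and validates the settings for [run_analysis()]: dataset roles,
#' instrument filters, estimator settings, the sensitivity ladder, and the
#' two-tier significance thresholds (strict Bonferroni tier and nominal
#' tier).
#'
#' @param exposure exposure summary data frame or file path.
#' @param outcomes named list of outcome summary data frames or paths.
#' @param mediator optional mediator summary data frame or path (enables the
#'   mediation analysis).
#' @param exclude_snps variant ids excluded in sensitivity analysis 1
#'   (e.g. SNPs associated with known confounders).
#' @param ld optional LD matrix (or path) enabling clumping.
#' @param p_threshold,maf_min,exclusion_regions instrument filters.
#' @param clump_r2,clump_window_kb clumping parameters.
#' @param steiger_p Steiger retention threshold (sensitivity analysis 2).
#' @param bootstrap_reps bootstrap size for median/mode SEs.
#' @param presso_nsim,presso_significance MR-PRESSO settings.
#' @param strict,nominal significance thresholds (`strict < nominal`).
#' @param run_pooled pool the outcome datasets and analyse the pooled trait.
#' @param run_reverse run the role-swapped (outcome -> exposure) analysis.
#' @param reverse_p_threshold instrument threshold for the reverse analysis.
#' @param seed master seed; every stochastic component derives its own
#'   stream from it.
#' @return Validated list of class `analysis_config`.
#' @export
analysis_config <- function(exposure, outcomes, mediator = NULL,
                            exclude_snps = character(0), ld = NULL,
                            p_threshold = 5e-8, maf_min = 0.01,
                            exclusion_regions = hla_region(),
                            clump_r2 = 0.01, clump_window_kb = 10000,
                            steiger_p = 0.01, bootstrap_reps = 1000,
                            presso_nsim = 1000, presso_significance = 0.05,
                            strict = 0.017, nominal = 0.05,
                            run_pooled = TRUE, run_reverse = TRUE,
                            reverse_p_threshold = 5e-8, seed = 1) {
  if (!(strict > 0 && strict < nominal && nominal < 1)) {
    stopf("need 0 < strict < nominal < 1 (got %g, %g)", strict, nominal)
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    stopf("outcomes must be a named list")
  }
  structure(list(exposure = exposure, outcomes = outcomes, mediator = mediator,
                 exclude_snps = exclude_snps, ld = ld,
                 p_threshold = p_threshold, maf_min = maf_min,
                 exclusion_regions = exclusion_regions,
                 clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
                 steiger_p = steiger_p, bootstrap_reps = bootstrap_reps,
                 presso_nsim = presso_nsim,
                 presso_significance = presso_significance,
                 strict = strict, nominal = nominal,
                 run_pooled = run_pooled, run_reverse = run_reverse,
                 reverse_p_threshold = reverse_p_threshold,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Significance labelling
#'
#' Two-tier policy: `"significant"` below the strict (multiplicity-adjusted)
#' threshold, `"nominal"` between the strict and nominal thresholds, `"null"`
#' otherwise. A p-value exactly at a threshold falls in the weaker category.
#'
#' @param pvalue p-value(s).
#' @param strict,nominal thresholds with `strict < nominal`.
#' @return Character vector in `{"significant", "nominal", "null"}`.
#' @export
label_significance <- function(pvalue, strict = 0.017, nominal = 0.05) {
  if (!(strict > 0 && strict < nominal && nominal < 1)) {
    stopf("need 0 < strict < nominal < 1")
  }
  ifelse(is.na(pvalue), NA_character_,
         ifelse(pvalue < strict, "significant",
                ifelse(pvalue < nominal, "nominal", "null")))
}

load_dataset <- function(x, trait_id = NULL) {
  if (is.character(x)) read_summary(x, trait_id = trait_id)
  else { validate_summary(x); x }
}

# One sensitivity ladder on a harmonized set: four nested instrument subsets,
# each analysed by the full estimator battery plus MR-PRESSO.
analyse_outcome_branch <- function(set, cfg, seed) {
  ladder <- list(
    primary = set,
    excl_pleiotropic = subset_set(set, drop_ids = cfg$exclude_snps),
    steiger = steiger_filter(set, cfg$steiger_p)$set
  )
  ladder$excl_both <- steiger_filter(ladder$excl_pleiotropic, cfg$steiger_p)$set
  out <- list()
  for (i in seq_along(ladder)) {
    lvl <- names(ladder)[i]
    sub <- ladder[[i]]
    ests <- mr_all(sub, bootstrap_reps = cfg$bootstrap_reps,
                   seed = derive_seed(seed, 10 * i))
    pres <- tryCatch(
      mr_presso(sub, n_simulations = cfg$presso_nsim,
                seed = derive_seed(seed, 10 * i + 5),
                significance = cfg$presso_significance),
      error = function(e) e)
    if (!inherits(pres, "error")) {
      corrected <- pres$theta_corrected %||% pres$theta_raw
      ests$presso <- mr_estimate("presso", corrected$theta, corrected$se,
                                 n_snps = corrected$n_snps,
                                 extras = list(global_p = pres$global_p,
                                               n_outliers = length(pres$outlier_ids)))
    }
    for (m in names(ests)) {
      ests[[m]]$extras$significance <-
        label_significance(ests[[m]]$pvalue, cfg$strict, cfg$nominal)
    }
    out[[lvl]] <- list(n_snps = n_snps(sub), estimates = ests,
                       presso = if (!inherits(pres, "error")) pres else NULL)
  }
  out
}

reverse_branch <- function(exposure, outcome, cfg, seed) {
  rev_ins <- filter_instruments(outcome, cfg$reverse_p_threshold, cfg$maf_min,
                                exclusion_regions = cfg$exclusion_regions)$records
  if (nrow(rev_ins) < 2) return(list(skipped = "too few outcome-associated instruments"))
  set <- harmonize(rev_ins, exposure)
  before <- mr_ivw(set, mode = "mre")
  filt <- steiger_filter(set, cfg$steiger_p)
  after <- if (n_snps(filt$set) >= 1) mr_ivw(filt$set, mode = "mre")
  list(ivw = before, ivw_steiger = after,
       n_snps = n_snps(set), n_snps_steiger = n_snps(filt$set))
}

#' Run the full MR analysis
#'
#' Executes, per outcome: instrument selection (filters and optional
#' clumping), harmonization, the primary multiplicative-random-effects IVW
#' analysis with MR-Egger, weighted median, weighted mode and MR-PRESSO, and
#' the three-step sensitivity ladder (1: excluding a supplied
#' pleiotropic-SNP list; 2: Steiger filtering; 3: both). Optionally pools
#' the outcome datasets by fixed-effects meta-analysis and analyses the
#' pooled trait, runs the two-step mediation analysis when a mediator is
#' configured, and the role-swapped reverse analysis. Stage failures abort
#' only that outcome's branch.
#'
#' @param cfg an [analysis_config()].
#' @return Results bundle (class `mr_bundle`): nested list with instrument
#'   audit, per-outcome estimates by sensitivity level, pooled analysis,
#'   mediation, reverse analysis, seeds and a config hash.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  exposure <- load_dataset(cfg$exposure, "exposure")
  outcomes <- lapply(names(cfg$outcomes), function(nm) {
    load_dataset(cfg$outcomes[[nm]], nm)
  })
  names(outcomes) <- names(cfg$outcomes)

  filt <- filter_instruments(exposure, cfg$p_threshold, cfg$maf_min,
                             exclusion_regions = cfg$exclusion_regions)
  instruments <- filt$records
  if (!is.null(cfg$ld)) {
    ld <- if (is.character(cfg$ld)) read_ld_matrix(cfg$ld) else cfg$ld
    instruments <- clump(instruments, ld, cfg$clump_r2, cfg$clump_window_kb)
  }
  diagnostics <- instrument_diagnostics(instruments)

  bundle <- list(config_hash = object_hash(unclass(cfg)), seed = cfg$seed,
                 instrument_audit = filt$audit, diagnostics = diagnostics,
                 outcomes = list())
  for (i in seq_along(outcomes)) {
    nm <- names(outcomes)[i]
    bundle$outcomes[[nm]] <- tryCatch({
      set <- harmonize(instruments, outcomes[[i]])
      c(list(harmonization = set$provenance),
        list(levels = analyse_outcome_branch(set, cfg, derive_seed(cfg$seed, 100 * i))))
    }, error = function(e) list(error = sprintf("outcome '%s': %s", nm,
                                                conditionMessage(e))))
  }

  if (cfg$run_pooled && length(outcomes) >= 2) {
    bundle$pooled <- tryCatch({
      pooled <- pool_datasets(outcomes, trait_id = "pooled")
      set <- harmonize(instruments, pooled$records)
      c(list(pool_audit = pooled$audit, harmonization = set$provenance),
        list(levels = analyse_outcome_branch(set, cfg, derive_seed(cfg$seed, 7000))))
    }, error = function(e) list(error = paste("pooled:", conditionMessage(e))))
  }

  if (!is.null(cfg$mediator)) {
    bundle$mediation <- tryCatch({
      mediator <- load_dataset(cfg$mediator, "mediator")
      target <- if (!is.null(bundle$pooled) && is.null(bundle$pooled$error)) {
        pool_datasets(outcomes, trait_id = "pooled")$records
      } else {
        outcomes[[1]]
      }
      mediation_pipeline(exposure, mediator, target,
                         p_threshold = cfg$p_threshold, maf_min = cfg$maf_min,
                         presso_sims = cfg$presso_nsim,
                         bootstrap_reps = max(cfg$bootstrap_reps, 1000),
                         seed = derive_seed(cfg$seed, 8000))
    }, error = function(e) list(error = paste("mediation:", conditionMessage(e))))
  }

  if (cfg$run_reverse) {
    bundle$reverse <- lapply(seq_along(outcomes), function(i) {
      tryCatch(reverse_branch(exposure, outcomes[[i]], cfg,
                              derive_seed(cfg$seed, 9000 + i)),
               error = function(e) list(error = conditionMessage(e)))
    })
    names(bundle$reverse) <- names(outcomes)
  }
  structure(bundle, class = "mr_bundle")
}

#' Render a results bundle into report tables
#'
#' Emits one row per (outcome, sensitivity level, method) with the estimate
#' on both scales, its p-value and significance label — every number taken
#' from the stored estimate objects, nothing recomputed — plus a metadata
#' block (seeds, config hash, package version). Regeneration from the same
#' bundle is byte-identical.
#'
#' @param bundle an `mr_bundle` from [run_analysis()].
#' @param out_dir optional directory; when given, writes `report.tsv` and
#'   `metadata.json` there.
#' @return list with `table` (data frame) and `metadata`.
#' @export
render_report <- function(bundle, out_dir = NULL) {
  branches <- bundle$outcomes
  if (!is.null(bundle$pooled)) branches$pooled <- bundle$pooled
  rows <- list()
  for (nm in names(branches)) {
    br <- branches[[nm]]
    if (!is.null(br$error)) next
    for (lvl in names(br$levels)) {
      ests <- br$levels[[lvl]]$estimates
      for (m in names(ests)) {
        e <- ests[[m]]
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = nm, sensitivity = lvl, method = e$method,
          n_snps = e$n_snps, theta = e$theta, se = e$se, or = exp(e$theta),
          or_ci_low = exp(e$ci_low), or_ci_high = exp(e$ci_high),
          pvalue = e$pvalue,
          significance = e$extras$significance %||% NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  metadata <- list(config_hash = bundle$config_hash, seed = bundle$seed,
                   package_version = as.character(utils::packageVersion("mrflow")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(table, file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_json_report(metadata, file.path(out_dir, "metadata.json"))
  }
  list(table = table, metadata = metadata)
}
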