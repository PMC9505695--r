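# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG state
#'
#' Seeds the global RNG, runs `code`, and restores the previous RNG state so
#' that seeded routines never perturb the caller's random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed for component `offset` from a master
# seed; keeps the result a valid positive 32-bit integer.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) * 7919 + as.numeric(offset) * 104729
  as.integer(s %% 2147483629 + 1)
}

# Two-sided p-value from a z statistic.
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

# Two-sided p-value from a t statistic with df degrees of freedom.
p_from_t <- function(t, df) 2 * stats::pt(-abs(t), df = df)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Hash of an R object via its serialized representation; used to stamp
# analysis bundles with a config fingerprint.
object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  # version = 2 keeps the serialization stable across R sessions
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

# jsonlite writer with the conventions used throughout the package.
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
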