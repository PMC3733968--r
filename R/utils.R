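# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named stage from a root seed, so that
# adding replicates to one stage never perturbs the random stream of another.
# Kept strictly below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  offsets <- c(
    pedigree = 101L, genotypes = 211L, genes = 307L, traits = 401L,
    effects = 503L, permutation = 601L, pipeline = 701L
  )
  off <- offsets[[stage]]
  if (is.null(off)) off <- sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Lower Cholesky-like factor of a symmetric PSD matrix; falls back to an
# eigenvalue-clipped square root (with a warning) when chol() fails because
# the matrix is singular or slightly indefinite from rounding.
psd_factor <- function(S, warn_label = "matrix") {
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (is.null(L)) {
    warning(sprintf("%s is singular; using eigenvalue-clipped factorization",
                    warn_label), call. = FALSE)
    es <- eigen(S, symmetric = TRUE)
    vals <- pmax(es$values, 0)
    L <- es$vectors %*% diag(sqrt(vals), nrow = length(vals))
  }
  L
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single number in (0, 1)", name), call. = FALSE)
  }
  invisible(x)
}
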