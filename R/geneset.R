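#' Proportion of significant SNPs in a set
#'
#' The set-level test statistic (the "f-value"): the number of SNPs with
#' `p <= alpha` (inclusive threshold) divided by the number of SNPs
#' tested.  Monomorphic or otherwise untested SNPs must be removed before
#' calling.
#'
#' @param p_values Numeric vector of per-SNP p-values in `[0, 1]`.
#' @param alpha Significance threshold (default 0.05).
#' @return A list with `n_significant` and `proportion`.
#' @export
#' @examples
#' proportion_significant(c(0.01, 0.05, 0.2, 0.8))  # 2 of 4
proportion_significant <- function(p_values, alpha = 0.05) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) {
    stop("no p-values supplied: the proportion is undefined", call. = FALSE)
  }
  if (any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n_sig <- sum(p_values <= alpha)
  list(n_significant = n_sig, proportion = n_sig / length(p_values))
}

#' Random-gene-set permutation null distribution
#'
#' Draws `n_reps` random sets of `n_genes` genes (uniformly, without
#' replacement) from a gene universe, builds the same flanked windows as
#' for the tested pathway, assigns SNPs with deduplication, and records
#' each set's proportion of significant SNPs.  Per-SNP p-values do not
#' depend on set membership, so they are computed once genome-wide and
#' reused across replicates.  Replicates whose windows contain no SNPs are
#' redrawn (counted in the `redraws` attribute).
#'
#' @param assoc Association results for one trait: a data frame with
#'   `snp_id` and `p_value` covering all genome SNPs (monomorphic rows are
#'   dropped internally).
#' @param gene_universe Gene annotation tibble to sample from.
#' @param snp_map SNP map tibble.
#' @param n_genes Number of genes per random set (default 11).
#' @param flank Window flank in bp (default 500 kb).
#' @param n_reps Number of permutation replicates (default 10,000).
#' @param alpha Per-SNP significance threshold.
#' @param seed Integer seed for the gene sampling.
#' @param redraw_cap Maximum total draws before giving up on SNP-less
#'   universes (default `100 * n_reps`).
#' @return Numeric vector of length `n_reps` of null proportions, with
#'   attributes `redraws` (number of empty sets redrawn) and `set_sizes`
#'   (unique SNP count per replicate).
#' @export
permutation_null <- function(assoc, gene_universe, snp_map,
                             n_genes = 11L, flank = 5e5,
                             n_reps = 10000L, alpha = 0.05,
                             seed = 1L, redraw_cap = NULL) {
  if (n_reps < 1) stop("no replicates requested", call. = FALSE)
  if (nrow(gene_universe) <= n_genes) {
    stop("gene universe must be larger than `n_genes`", call. = FALSE)
  }
  assert_prob(alpha, "alpha")
  redraw_cap <- redraw_cap %||% (100 * n_reps)

  assoc <- dplyr::filter(assoc, !is.na(.data$p_value))
  p <- stats::setNames(assoc$p_value, assoc$snp_id)

  # windows depend only on the gene, so pre-assign SNPs per gene once
  win <- build_windows(gene_universe, flank = flank)
  members <- suppressWarnings(assign_snps(win, snp_map))$members
  members <- dplyr::filter(members, .data$snp_id %in% names(p))
  gene_snps <- split(match(members$snp_id, names(p)), members$gene_id)
  gene_snps <- gene_snps[gene_universe$gene_id[
    gene_universe$gene_id %in% names(gene_snps)]]
  sig <- unname(p) <= alpha

  set.seed(seed)
  ng_univ <- nrow(gene_universe)
  out <- numeric(n_reps)
  sizes <- integer(n_reps)
  redraws <- 0L
  draws <- 0L
  i <- 1L
  while (i <= n_reps) {
    draws <- draws + 1L
    if (draws > redraw_cap) {
      stop("redraw cap reached: the gene universe has almost no SNP ",
           "coverage", call. = FALSE)
    }
    pick <- gene_universe$gene_id[sample.int(ng_univ, n_genes)]
    idx <- unique(unlist(gene_snps[pick], use.names = FALSE))
    if (!length(idx)) {
      redraws <- redraws + 1L
      next
    }
    out[i] <- mean(sig[idx])
    sizes[i] <- length(idx)
    i <- i + 1L
  }
  attr(out, "redraws") <- redraws
  attr(out, "set_sizes") <- sizes
  out
}

#' Experiment-wise significance from a permutation null
#'
#' The fraction of null replicates whose proportion of significant SNPs
#' meets or exceeds the observed proportion.  Counting ties as exceeding
#' (`ties = "ge"`, the default) is the conservative convention; a strict
#' `>` variant is available.
#'
#' @param observed Observed proportion significant.
#' @param null_proportions Vector from [permutation_null()].
#' @param ties `"ge"` (null >= observed counts) or `"gt"` (strict).
#' @return A single fraction in `[0, 1]`.
#' @export
experimentwise_p <- function(observed, null_proportions,
                             ties = c("ge", "gt")) {
  ties <- match.arg(ties)
  if (!length(null_proportions)) {
    stop("empty null distribution", call. = FALSE)
  }
  if (ties == "ge") {
    mean(null_proportions >= observed)
  } else {
    mean(null_proportions > observed)
  }
}

#' False discovery rate as m*P/S
#'
#' The study-style FDR at a fixed per-test threshold: the expected number
#' of false positives `m * P` divided by the observed number of
#' significant tests `S`, expressed as a percent.  Table-style reporting
#' truncates the percent toward zero (the only convention consistent with
#' published tables of this statistic); the raw percent is also returned.
#' With `S = 0` the rate is undefined (`NA`).
#'
#' @param m Number of tests.
#' @param p Per-test significance threshold (e.g. 0.05).
#' @param s Number of tests significant at that threshold.
#' @return A list with `raw_percent` and `percent` (truncated integer).
#' @export
#' @examples
#' fdr_mps(211, 0.05, 57)$percent  # 18
fdr_mps <- function(m, p, s) {
  stopifnot(m >= 1, s >= 0)
  assert_prob(p, "p")
  if (s == 0) {
    return(list(raw_percent = NA_real_, percent = NA_integer_))
  }
  raw <- 100 * m * p / s
  list(raw_percent = raw, percent = as.integer(trunc(raw)))
}

#' Pathway SNP-set association test
#'
#' End-to-end set-level inference for one trait: builds the pathway's
#' flanked windows, collects its deduplicated SNP set, computes the
#' proportion of set SNPs significant at `alpha`, compares it against a
#' random-gene-set permutation null to obtain an experiment-wise P, and
#' reports the m*P/S FDR.
#'
#' @param assoc Per-SNP association results for one trait (`snp_id`,
#'   `p_value`, optionally `trait`), covering all genome SNPs.
#' @param pathway_genes Gene annotation tibble for the pathway genes.
#' @param gene_universe Gene annotation tibble to draw random sets from.
#' @param snp_map SNP map tibble.
#' @param flank Window flank in bp.
#' @param alpha Per-SNP significance threshold.
#' @param n_reps Number of permutation replicates.
#' @param seed Seed for the permutation sampling.
#' @param ties Tie convention for the experiment-wise P, see
#'   [experimentwise_p()].
#' @return An object of class `pathway_test` with the observed counts,
#'   the null distribution, `experimentwise_p` and the FDR; see
#'   [tidy.pathway_test()], [glance.pathway_test()] and
#'   [autoplot.pathway_test()].
#' @export
pathway_test <- function(assoc, pathway_genes, gene_universe, snp_map,
                         flank = 5e5, alpha = 0.05, n_reps = 10000L,
                         seed = 1L, ties = "ge") {
  trait <- if ("trait" %in% names(assoc)) {
    tr <- unique(assoc$trait)
    if (length(tr) != 1) {
      stop("`assoc` must contain a single trait; filter first",
           call. = FALSE)
    }
    tr
  } else "trait"
  win <- build_windows(pathway_genes, flank = flank)
  sset <- assign_snps(win, snp_map)
  assoc_ok <- dplyr::filter(assoc, !is.na(.data$p_value))
  p_set <- assoc_ok$p_value[assoc_ok$snp_id %in% sset$snp_ids]
  obs <- proportion_significant(p_set, alpha)
  null <- permutation_null(assoc_ok, gene_universe, snp_map,
                           n_genes = nrow(pathway_genes), flank = flank,
                           n_reps = n_reps, alpha = alpha, seed = seed)
  ep <- experimentwise_p(obs$proportion, null, ties = ties)
  fdr <- fdr_mps(length(p_set), alpha, obs$n_significant)
  structure(list(
    trait = trait,
    n_snps_tested = length(p_set),
    n_significant = obs$n_significant,
    proportion_significant = obs$proportion,
    alpha = alpha,
    null_proportions = as.numeric(null),
    experimentwise_p = ep,
    fdr_percent = fdr$percent,
    fdr_raw_percent = fdr$raw_percent,
    snp_set = sset,
    n_reps = n_reps,
    redraws = attr(null, "redraws"),
    seed = seed
  ), class = "pathway_test")
}

#' @export
print.pathway_test <- function(x, ...) {
  cat(sprintf("<pathway_test> trait %s\n", x$trait))
  cat(sprintf("  %d of %d set SNPs significant at alpha = %g (f = %.3f)\n",
              x$n_significant, x$n_snps_tested, x$alpha,
              x$proportion_significant))
  cat(sprintf("  experiment-wise P = %.4f (%d random gene sets)\n",
              x$experimentwise_p, x$n_reps))
  cat(sprintf("  FDR (m*P/S) = %s%%\n",
              ifelse(is.na(x$fdr_percent), "NA", x$fdr_percent)))
  invisible(x)
}
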