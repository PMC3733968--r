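#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object.  The defaults emulate the statistical structure of a national
#' dairy-bull reference population: ~2,154 genotyped bulls descending from a
#' multi-generation pedigree, ~43k genome-wide SNPs with strong local LD,
#' and six correlated traits (daughter trait deviations) composed of
#' polygenic and residual variation.  Tests and examples pass much smaller
#' values explicitly.
#'
#' @param n_founders Number of unrelated base-population animals.
#' @param n_generations Total number of generations including the founders;
#'   `1` means a founder-only population.
#' @param n_animals Total number of animals across all generations.
#' @param n_chromosomes Number of autosomes to simulate.
#' @param chrom_length_bp Length of each chromosome in base pairs.
#' @param n_snps Total number of SNPs, split evenly across chromosomes.
#' @param maf_range Length-2 numeric; founder minor-allele frequencies are
#'   drawn uniformly from this interval (bounds in (0, 0.5]).
#' @param ld_decay_rho Copying probability of the founder-haplotype Markov
#'   chain in `[0, 1)`: with probability `ld_decay_rho` an adjacent founder
#'   allele is copied from its neighbour, otherwise it is drawn fresh.
#'   Controls the decay of linkage disequilibrium.
#' @param n_genes Number of annotated genes to scatter on the genome.
#' @param gene_length_range Length-2 numeric, gene lengths in bp.
#' @param n_traits Number of traits.
#' @param trait_means Numeric vector of per-trait means (recycled).
#' @param sigma_a2,sigma_e2 Per-trait additive-genetic and residual
#'   variances (recycled to `n_traits`).
#' @param genetic_corr Trait x trait additive-genetic correlation matrix;
#'   must be symmetric with unit diagonal and positive semi-definite.
#' @param unknown_parent_prob Probability that a non-founder has an unknown
#'   sire (and, independently, dam).
#' @param pathway_gene_ids Character vector of gene ids that form the
#'   "pathway" whose windows may carry true SNP effects.
#' @param pathway_effect_sizes Named list mapping SNP id to a numeric vector
#'   of per-allele effects (one per trait).  Usually filled by
#'   [embed_pathway_effects()].
#' @param qtl_snp Optional id of a single SNP given a large effect (a
#'   DGAT1-like QTL); see `qtl_effect`.
#' @param qtl_effect Per-allele effect vector (one per trait) for `qtl_snp`.
#' @param seed Integer root seed; the same seed reproduces every output
#'   bit-for-bit.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_dataset()], [simulate_pedigree()]
#' @export
#' @examples
#' cfg <- sim_config(n_founders = 20, n_generations = 3, n_animals = 60,
#'                   n_chromosomes = 2, n_snps = 100, n_genes = 10,
#'                   n_traits = 2, seed = 1)
#' cfg$n_animals
sim_config <- function(n_founders = 400,
                       n_generations = 6,
                       n_animals = 2154,
                       n_chromosomes = 29,
                       chrom_length_bp = 1.1e8,
                       n_snps = 43115,
                       maf_range = c(0.05, 0.5),
                       ld_decay_rho = 0.9,
                       n_genes = 1000,
                       gene_length_range = c(5e3, 1e5),
                       n_traits = 6,
                       trait_means = 0,
                       sigma_a2 = 0.3,
                       sigma_e2 = 0.7,
                       genetic_corr = diag(n_traits),
                       unknown_parent_prob = 0,
                       pathway_gene_ids = character(),
                       pathway_effect_sizes = list(),
                       qtl_snp = NULL,
                       qtl_effect = NULL,
                       seed = 1L) {
  stopifnot(n_founders >= 1, n_generations >= 1, n_animals >= n_founders,
            n_chromosomes >= 1, n_snps >= 1, n_genes >= 0, n_traits >= 1,
            chrom_length_bp >= 1)
  if (n_generations > 1 && n_founders < 2) {
    stop("at least two founders are required to breed later generations",
         call. = FALSE)
  }
  if (n_snps < n_chromosomes) {
    stop("`n_snps` must be at least `n_chromosomes`", call. = FALSE)
  }
  maf_range <- as.numeric(maf_range)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an increasing pair within (0, 0.5]",
         call. = FALSE)
  }
  if (!is.numeric(ld_decay_rho) || ld_decay_rho < 0 || ld_decay_rho >= 1) {
    stop("`ld_decay_rho` must lie in [0, 1)", call. = FALSE)
  }
  if (unknown_parent_prob < 0 || unknown_parent_prob > 1) {
    stop("`unknown_parent_prob` must lie in [0, 1]", call. = FALSE)
  }
  trait_means <- rep_len(as.numeric(trait_means), n_traits)
  sigma_a2 <- rep_len(as.numeric(sigma_a2), n_traits)
  sigma_e2 <- rep_len(as.numeric(sigma_e2), n_traits)
  if (any(sigma_a2 < 0) || any(sigma_e2 < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  genetic_corr <- as.matrix(genetic_corr)
  if (!isTRUE(all.equal(genetic_corr, t(genetic_corr), tolerance = 1e-10)) ||
      nrow(genetic_corr) != n_traits ||
      !isTRUE(all.equal(unname(diag(genetic_corr)), rep(1, n_traits),
                        tolerance = 1e-10))) {
    stop("`genetic_corr` must be a symmetric unit-diagonal matrix of size ",
         "n_traits", call. = FALSE)
  }
  if (min(eigen(genetic_corr, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("`genetic_corr` must be positive semi-definite", call. = FALSE)
  }
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_animals = as.integer(n_animals),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_snps = as.integer(n_snps),
    maf_range = maf_range,
    ld_decay_rho = as.numeric(ld_decay_rho),
    n_genes = as.integer(n_genes),
    gene_length_range = as.numeric(gene_length_range),
    n_traits = as.integer(n_traits),
    trait_names = paste0("trait_", seq_len(n_traits)),
    trait_means = trait_means,
    sigma_a2 = sigma_a2,
    sigma_e2 = sigma_e2,
    genetic_corr = genetic_corr,
    unknown_parent_prob = as.numeric(unknown_parent_prob),
    pathway_gene_ids = as.character(pathway_gene_ids),
    pathway_effect_sizes = pathway_effect_sizes,
    qtl_snp = qtl_snp,
    qtl_effect = qtl_effect,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  animals: %d (%d founders, %d generations)\n",
              x$n_animals, x$n_founders, x$n_generations))
  cat(sprintf("  genome: %d SNPs on %d chromosomes, %d genes\n",
              x$n_snps, x$n_chromosomes, x$n_genes))
  cat(sprintf("  traits: %d (h2 = %s)\n", x$n_traits,
              paste(signif(x$sigma_a2 / (x$sigma_a2 + x$sigma_e2), 3),
                    collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
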