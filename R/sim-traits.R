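#' Simulate correlated polygenic traits
#'
#' Generates one record per animal for each trait from the generative form
#' of the association model:
#' \deqn{y_t = \mu_t + \sum_j x_j \beta_{jt} + u_t + e_t,}
#' where the polygenic vectors across traits follow the Kronecker
#' covariance \eqn{(\mathrm{diag}(\sigma_a) R \,\mathrm{diag}(\sigma_a))
#' \otimes A} with \eqn{R} the genetic correlation matrix and \eqn{A} the
#' numerator relationship matrix, and residuals are independent
#' \eqn{N(0, \sigma^2_{e,t})}.  SNP effects come from
#' `config$pathway_effect_sizes` plus the optional `qtl_snp`/`qtl_effect`
#' pair.
#'
#' @param pedigree Pedigree tibble; defines the animals and their order.
#' @param genotypes Animal x SNP genotype matrix (may be `NULL` when no SNP
#'   effects are configured).
#' @param A Numerator relationship matrix from [kinship_matrix()], with ids
#'   as dimnames, covering every pedigree animal.
#' @param config A [sim_config()] object.
#' @return A tibble with `animal_id` and one column per trait.
#' @export
simulate_traits <- function(pedigree, genotypes, A, config) {
  stopifnot(inherits(config, "sim_config"))
  ped <- normalize_pedigree(pedigree)
  ids <- ped$id
  n <- length(ids)
  nt <- config$n_traits
  if (!all(ids %in% rownames(A))) {
    stop("`A` does not cover every pedigree animal", call. = FALSE)
  }
  A <- A[ids, ids, drop = FALSE]
  set.seed(stage_seed(config$seed, "traits"))

  sig_g <- diag(sqrt(config$sigma_a2), nt) %*% config$genetic_corr %*%
    diag(sqrt(config$sigma_a2), nt)
  u <- matrix(0, n, nt)
  if (any(config$sigma_a2 > 0)) {
    La <- psd_factor(A, "relationship matrix")
    Lg <- psd_factor(sig_g, "genetic covariance matrix")
    u <- La %*% matrix(stats::rnorm(n * nt), n, nt) %*% t(Lg)
  }
  e <- matrix(stats::rnorm(n * nt), n, nt) %*%
    diag(sqrt(config$sigma_e2), nt)

  y <- matrix(rep(config$trait_means, each = n), n, nt) + u + e

  effects <- config$pathway_effect_sizes
  if (!is.null(config$qtl_snp)) {
    effects[[config$qtl_snp]] <-
      rep_len(as.numeric(config$qtl_effect %||% 0), nt)
  }
  if (length(effects)) {
    missing_snps <- setdiff(names(effects), colnames(genotypes))
    if (length(missing_snps)) {
      stop("effect-bearing SNP(s) absent from the genotype table: ",
           paste(missing_snps, collapse = ", "), call. = FALSE)
    }
    X <- genotypes[ids, names(effects), drop = FALSE]
    B <- do.call(rbind, lapply(effects, rep_len, nt))
    y <- y + X %*% B
  }

  colnames(y) <- config$trait_names
  dplyr::bind_cols(tibble::tibble(animal_id = ids),
                   tibble::as_tibble(y))
}

#' Place true per-allele effects inside pathway gene windows
#'
#' Chooses one SNP per pathway gene (the SNP closest to the gene midpoint
#' within the flanked window) and sizes equal per-SNP variance
#' contributions so that the effects jointly explain a target fraction of
#' the trait variance: for a SNP with allele frequency \eqn{p}, a
#' per-allele effect \eqn{\beta} contributes \eqn{2p(1-p)\beta^2}.
#'
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `stop`).
#' @param pathway_gene_ids Genes whose windows receive an effect SNP.
#' @param snp_map SNP map tibble.
#' @param genotypes Genotype matrix used to estimate allele frequencies.
#' @param target_var_fraction Fraction of the total phenotypic variance
#'   (`sigma_a2 + sigma_e2` for the affected trait) explained jointly.
#' @param config A [sim_config()] object supplying variances and trait
#'   count.
#' @param traits Indices of the traits that receive the effects.
#' @param flank Window flank in bp.
#' @return A named list mapping SNP id to a per-trait effect vector,
#'   suitable for `pathway_effect_sizes` in [sim_config()].
#' @export
embed_pathway_effects <- function(genes, pathway_gene_ids, snp_map,
                                  genotypes, target_var_fraction,
                                  config, traits = 1L, flank = 5e5) {
  stopifnot(target_var_fraction >= 0)
  if (target_var_fraction == 0 || !length(pathway_gene_ids)) return(list())
  genes <- dplyr::filter(genes, .data$gene_id %in% pathway_gene_ids)
  win <- build_windows(genes, flank = flank)
  members <- assign_snps(win, snp_map)$members
  if (!nrow(members)) {
    stop("no SNPs fall inside the pathway gene windows", call. = FALSE)
  }
  mid <- stats::setNames((genes$start + genes$stop) / 2, genes$gene_id)
  chosen <- members |>
    dplyr::left_join(snp_map, by = "snp_id") |>
    dplyr::mutate(dist = abs(.data$pos - mid[.data$gene_id])) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  k <- nrow(chosen)
  total_var <- sum(config$sigma_a2[traits[1]], config$sigma_e2[traits[1]])
  share <- target_var_fraction * total_var / k
  freq <- colMeans(genotypes[, chosen$snp_id, drop = FALSE]) / 2
  het <- pmax(2 * freq * (1 - freq), 1e-6)
  beta <- sqrt(share / het)
  out <- purrr::map2(chosen$snp_id, beta, function(s, b) {
    eff <- rep(0, config$n_traits)
    eff[traits] <- b
    eff
  })
  stats::setNames(out, chosen$snp_id)
}

#' Simulate a complete study data set
#'
#' Runs the whole generator — pedigree, kinship, genotypes, gene
#' annotation, optional embedded pathway effects, traits — and returns all
#' pieces plus a `truth` record of what was simulated.
#'
#' @param config A [sim_config()] object.
#' @param pathway_n_genes Number of genes declared as the tested pathway.
#'   Used when `config$pathway_gene_ids` is empty: that many genes are
#'   sampled at random from the annotation.
#' @param pathway_h2 Fraction of trait variance jointly explained by true
#'   SNP effects placed in the pathway windows (0 = pure null).
#' @param pathway_traits Trait indices carrying those effects.
#' @param flank Window flank in bp used when placing effects.
#' @return A list of class `pathsnp_sim` with elements `pedigree`, `A`,
#'   `genotypes`, `snp_map`, `genes`, `phenotypes`, `config` and `truth`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_founders = 20, n_generations = 3,
#'                                    n_animals = 60, n_chromosomes = 2,
#'                                    n_snps = 200, n_genes = 12,
#'                                    n_traits = 2, seed = 11))
#' names(sim)
simulate_dataset <- function(config, pathway_n_genes = 11L,
                             pathway_h2 = 0, pathway_traits = 1L,
                             flank = 5e5) {
  stopifnot(inherits(config, "sim_config"))
  pedigree <- simulate_pedigree(config)
  A <- kinship_matrix(pedigree)
  geno <- simulate_genotypes(pedigree, config)
  genes <- simulate_genes(config)

  pathway_genes <- config$pathway_gene_ids
  if (!length(pathway_genes) && pathway_n_genes > 0 && nrow(genes)) {
    set.seed(stage_seed(config$seed, "effects"))
    pathway_genes <- sample(genes$gene_id, min(pathway_n_genes, nrow(genes)))
  }
  if (pathway_h2 > 0 && !length(config$pathway_effect_sizes)) {
    config$pathway_effect_sizes <- embed_pathway_effects(
      genes, pathway_genes, geno$snp_map, geno$genotypes,
      target_var_fraction = pathway_h2, config = config,
      traits = pathway_traits, flank = flank)
  }

  phen <- simulate_traits(pedigree, geno$genotypes, A, config)
  structure(list(
    pedigree = pedigree,
    A = A,
    genotypes = geno$genotypes,
    snp_map = geno$snp_map,
    genes = genes,
    phenotypes = phen,
    config = config,
    truth = list(
      pathway_gene_ids = pathway_genes,
      effect_sizes = config$pathway_effect_sizes,
      qtl_snp = config$qtl_snp,
      qtl_effect = config$qtl_effect,
      sigma_a2 = config$sigma_a2,
      sigma_e2 = config$sigma_e2,
      genetic_corr = config$genetic_corr,
      seed = config$seed
    )
  ), class = "pathsnp_sim")
}

#' @export
print.pathsnp_sim <- function(x, ...) {
  cat("<pathsnp_sim>\n")
  cat(sprintf("  %d animals, %d SNPs, %d genes, %d trait(s)\n",
              nrow(x$pedigree), ncol(x$genotypes), nrow(x$genes),
              x$config$n_traits))
  cat(sprintf("  pathway: %d gene(s), %d true effect SNP(s)\n",
              length(x$truth$pathway_gene_ids),
              length(x$truth$effect_sizes)))
  invisible(x)
}
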