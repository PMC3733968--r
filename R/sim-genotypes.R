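#' Simulate LD-structured genotypes down a pedigree
#'
#' Founder haplotypes are drawn from a first-order Markov "copying" chain:
#' each SNP's allele is determined by a latent uniform that is, with
#' probability `ld_decay_rho`, copied from the adjacent SNP and otherwise
#' drawn fresh, so adjacent founder alleles have correlation
#' `ld_decay_rho` (exactly so when their allele frequencies are equal)
#' while every SNP keeps its own marginal frequency.  Offspring receive one
#' gamete per parent by Mendelian transmission with a single uniformly
#' placed crossover per chromosome per meiosis.  Gametes from an unknown
#' parent are drawn fresh from the base population.
#'
#' @param pedigree Pedigree tibble (`id`, `sire`, `dam`); processed in
#'   topological order.
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{genotypes}{integer matrix, animals x SNPs, entries 0/1/2 =
#'       count of the allele whose founder frequency was drawn from
#'       `maf_range`; dimnames are animal ids and SNP ids.}
#'     \item{snp_map}{tibble `snp_id`, `chrom`, `pos` (1-based, strictly
#'       increasing within chromosome).}
#'   }
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  ped <- normalize_pedigree(pedigree)
  ord <- pedigree_toposort(ped)
  set.seed(stage_seed(config$seed, "genotypes"))

  n <- nrow(ped)
  m <- config$n_snps
  nc <- config$n_chromosomes
  per_chr <- diff(round(seq(0, m, length.out = nc + 1)))
  chrom <- rep(seq_len(nc), per_chr)
  pos <- unlist(lapply(per_chr, function(k) {
    sort(sample.int(config$chrom_length_bp, k))
  }), use.names = FALSE)
  snp_id <- sprintf("snp%05d", seq_len(m))
  snp_map <- tibble::tibble(snp_id = snp_id,
                            chrom = paste0("chr", chrom),
                            pos = as.integer(pos))

  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  rho <- config$ld_decay_rho
  chr_start <- c(TRUE, chrom[-1] != chrom[-m])

  # one base-population haplotype per row of `k`
  base_haplotypes <- function(k) {
    u <- matrix(stats::runif(k * m), k, m)
    if (rho > 0 && m > 1) {
      for (j in 2:m) {
        if (chr_start[j]) next
        keep <- stats::runif(k) < rho
        u[keep, j] <- u[keep, j - 1]
      }
    }
    (u < rep(p, each = k)) + 0L
  }

  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  sire <- match(ped$sire, ped$id)
  dam <- match(ped$dam, ped$id)

  chr_of <- chrom
  gamete <- function(ha, hb) {
    # single crossover per chromosome, uniform position; random start strand
    x <- stats::runif(nc, 0, config$chrom_length_bp)
    start1 <- stats::runif(nc) < 0.5
    before <- pos <= x[chr_of]
    take1 <- ifelse(before, start1[chr_of], !start1[chr_of])
    ifelse(take1, ha, hb)
  }

  for (i in ord) {
    s <- sire[i]
    d <- dam[i]
    if (is.na(s) && is.na(d)) {
      hf <- base_haplotypes(2L)
      h1[i, ] <- hf[1, ]
      h2[i, ] <- hf[2, ]
    } else {
      h1[i, ] <- if (is.na(s)) base_haplotypes(1L)[1, ] else
        gamete(h1[s, ], h2[s, ])
      h2[i, ] <- if (is.na(d)) base_haplotypes(1L)[1, ] else
        gamete(h1[d, ], h2[d, ])
    }
  }

  g <- h1 + h2
  dimnames(g) <- list(ped$id, snp_id)
  list(genotypes = g, snp_map = snp_map)
}

#' Scatter gene annotations across the simulated genome
#'
#' Genes get uniform random start positions and lengths drawn from
#' `gene_length_range`; coordinates are 1-based and inclusive.
#'
#' @param config A [sim_config()] object.
#' @return A tibble `gene_id`, `chrom`, `start`, `stop`.
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genes"))
  ng <- config$n_genes
  if (ng == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), stop = integer()))
  }
  chrom <- sample.int(config$n_chromosomes, ng, replace = TRUE)
  len <- round(stats::runif(ng, config$gene_length_range[1],
                            config$gene_length_range[2]))
  start <- pmax(1, round(stats::runif(ng, 1, config$chrom_length_bp - len)))
  tibble::tibble(gene_id = sprintf("gene%04d", seq_len(ng)),
                 chrom = paste0("chr", chrom),
                 start = as.integer(start),
                 stop = as.integer(start + len - 1))
}
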