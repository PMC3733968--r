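#' @title Readers and writers for the pipeline's flat-file formats
#' @description
#' All interchange formats are tab-separated text: pedigree
#' (`id, sire, dam`; 0 or empty = unknown), genotypes (rows = animals,
#' columns = SNP ids, values 0/1/2), SNP map (`snp_id, chrom, pos`
#' 1-based), gene annotation (`gene_id, chrom, start, stop` 1-based
#' inclusive, or BED converted on read), phenotypes (`animal_id` + trait
#' columns) and the A matrix (ids as header row and first column).
#' @name pathsnpset_io
NULL

#' @rdname pathsnpset_io
#' @param path File path.
#' @return `read_pedigree()`: tibble `id`, `sire`, `dam` (`NA` = unknown).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  names(ped)[1:3] <- c("id", "sire", "dam")
  normalize_pedigree(ped)
}

#' @rdname pathsnpset_io
#' @param pedigree Pedigree tibble.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- dplyr::mutate(
    normalize_pedigree(pedigree),
    sire = dplyr::coalesce(.data$sire, "0"),
    dam = dplyr::coalesce(.data$dam, "0"))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname pathsnpset_io
#' @return `read_genotypes()`: integer matrix, animals x SNPs.
#' @export
read_genotypes <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    animal_id = "c", .default = "i"))
  g <- as.matrix(tab[-1])
  rownames(g) <- tab$animal_id
  g
}

#' @rdname pathsnpset_io
#' @param genotypes Genotype matrix with animal ids as rownames.
#' @export
write_genotypes <- function(genotypes, path) {
  tab <- dplyr::bind_cols(tibble::tibble(animal_id = rownames(genotypes)),
                          tibble::as_tibble(genotypes))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname pathsnpset_io
#' @return `read_snp_map()`: tibble `snp_id`, `chrom`, `pos`.
#' @export
read_snp_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    snp_id = "c", chrom = "c", pos = "i"))
}

#' @rdname pathsnpset_io
#' @return `read_genes()`: tibble `gene_id`, `chrom`, `start`, `stop`
#'   (1-based inclusive).  BED input (`.bed`, 0-based half-open) is
#'   converted by adding 1 to the start.
#' @export
read_genes <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- readr::read_tsv(path, col_names = FALSE,
                           col_types = readr::cols(.default = "c"))
    return(tibble::tibble(gene_id = bed[[4]],
                          chrom = bed[[1]],
                          start = as.integer(bed[[2]]) + 1L,
                          stop = as.integer(bed[[3]])))
  }
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", chrom = "c", start = "i", stop = "i"))
}

#' @rdname pathsnpset_io
#' @param genes Gene annotation tibble.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- tibble::tibble(chrom = genes$chrom,
                        start = genes$start - 1L,
                        stop = genes$stop,
                        name = genes$gene_id)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname pathsnpset_io
#' @return `read_phenotypes()`: tibble `animal_id` + numeric trait
#'   columns.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    animal_id = "c", .default = "d"))
}

#' @rdname pathsnpset_io
#' @param A Relationship matrix.
#' @export
write_kinship <- function(A, path) {
  tab <- dplyr::bind_cols(tibble::tibble(id = rownames(A)),
                          tibble::as_tibble(A))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname pathsnpset_io
#' @return `read_kinship()`: numeric matrix with ids as dimnames.
#' @export
read_kinship <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    id = "c", .default = "d"))
  A <- as.matrix(tab[-1])
  rownames(A) <- tab$id
  A
}

#' Read 0/1/2 genotypes from a VCF file
#'
#' Converts the GT field of a VCF into an allele-count matrix (count of
#' the ALT allele; missing calls become `NA`) plus a SNP map taken from
#' CHROM/POS/ID.  Requires the `vcfR` package.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return A list with `genotypes` (animals x SNPs) and `snp_map`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a) {
             sum(as.integer(a)) }, integer(1)))
  }
  gm <- apply(gt, 2, count_alt)
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  g <- t(gm)
  colnames(g) <- ids
  list(genotypes = g,
       snp_map = tibble::tibble(snp_id = ids,
                                chrom = fix[, "CHROM"],
                                pos = as.integer(fix[, "POS"])))
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT fields only (unphased, REF=A/ALT=B
#' placeholders); the counted allele is written as ALT.
#'
#' @param genotypes Animal x SNP 0/1/2 matrix.
#' @param snp_map SNP map tibble aligned to the matrix columns.
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(genotypes, snp_map, path) {
  stopifnot(identical(colnames(genotypes), snp_map$snp_id))
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(snp_map$chrom[j], snp_map$pos[j], snp_map$snp_id[j],
            "A", "B", ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write every artifact of a simulated data set
#'
#' @param sim A `pathsnp_sim` object from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param vcf Also write the genotypes as VCF?
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir, vcf = FALSE) {
  stopifnot(inherits(sim, "pathsnp_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.tsv"))
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(sim$snp_map, file.path(dir, "snp_map.tsv"))
  readr::write_tsv(sim$genes, file.path(dir, "genes.tsv"))
  write_genes_bed(sim$genes, file.path(dir, "genes.bed"))
  readr::write_tsv(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  if (vcf) {
    write_genotypes_vcf(sim$genotypes, sim$snp_map,
                        file.path(dir, "genotypes.vcf"))
  }
  truth <- sim$truth
  truth$genetic_corr <- as.data.frame(truth$genetic_corr)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
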