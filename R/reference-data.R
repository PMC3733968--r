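#' Published RNASE5-pathway reference tables
#'
#' The 11-gene RNASE5 pathway of Holstein-Friesian dairy cattle, as
#' published: per-gene flanked SNP regions (gene window plus 500 kb on
#' either side, 1-based bp, bovine genome Build 4.0 coordinates), the
#' number of 50k-chip SNPs in each window, and the number of those SNPs
#' significant at P <= 0.05 for each of the six milk production and
#' fertility traits.  These tables are shipped as plain-text inputs for
#' worked examples and for reproducing the published set-level arithmetic
#' (f-values and m*P/S false discovery rates).
#'
#' @return A list with
#'   \describe{
#'     \item{windows}{tibble `gene_id`, `chrom`, `win_start`, `win_stop`,
#'       `n_snps`;}
#'     \item{sig_counts}{tibble `gene_id` plus one count column per trait
#'       (`protein_yield`, `protein_pct`, `fertility`, `fat_yield`,
#'       `fat_pct`, `milk_yield`);}
#'     \item{m}{total number of SNPs in the deduplicated pathway set
#'       (211).}
#'   }
#' @export
#' @examples
#' ref <- rnase5_reference()
#' ref$m
#' colSums(ref$sig_counts[-1])  # per-trait significant totals
rnase5_reference <- function() {
  win <- readr::read_tsv(
    system.file("extdata", "rnase5_pathway_windows.tsv",
                package = "pathsnpset"),
    col_types = readr::cols(gene_id = "c", chrom = "c", win_start = "d",
                            win_stop = "d", n_snps = "i"))
  sig <- readr::read_tsv(
    system.file("extdata", "rnase5_sig_counts.tsv",
                package = "pathsnpset"),
    col_types = readr::cols(gene_id = "c", .default = "i"))
  list(windows = win, sig_counts = sig, m = sum(win$n_snps))
}
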