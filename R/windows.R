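#' Build flanked gene windows
#'
#' Expands each gene annotation by a fixed flank on both sides:
#' `win_start = max(1, start - flank)`, `win_stop = stop + flank`.
#' Coordinates are 1-based and inclusive at both ends.  Windows are kept
#' per gene and never merged, so overlapping windows are allowed.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`,
#'   `stop` (1-based inclusive).
#' @param flank Flank size in bp on either side of the gene (default
#'   500 kb, reflecting the extent of linkage disequilibrium in dairy
#'   cattle populations).
#' @return A tibble `gene_id`, `chrom`, `win_start`, `win_stop`.
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = "ACTA2", chrom = "26",
#'                         start = 11078865, stop = 11092811)
#' build_windows(genes)  # window 10578865..11592811
build_windows <- function(genes, flank = 5e5) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "stop") %in% names(genes)))
  if (flank < 0) stop("`flank` must be non-negative", call. = FALSE)
  bad <- genes$start > genes$stop
  if (any(bad)) {
    stop("gene annotation has start > stop for: ",
         paste(genes$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  genes |>
    dplyr::transmute(
      gene_id = as.character(.data$gene_id),
      chrom = as.character(.data$chrom),
      win_start = pmax(1, .data$start - flank),
      win_stop = .data$stop + flank
    )
}

#' Assign SNPs to gene windows
#'
#' A SNP belongs to a window when it lies on the same chromosome and
#' `win_start <= pos <= win_stop` (both ends inclusive).  A SNP falling in
#' several overlapping windows is counted once per window in the per-gene
#' counts but only once in the deduplicated SNP set — the convention needed
#' so that a set-level total can be smaller than the sum of per-gene
#' counts.
#'
#' @param windows Tibble from [build_windows()].
#' @param snp_map Data frame `snp_id`, `chrom`, `pos`.
#' @return An object of class `snp_set`: a list with
#'   \describe{
#'     \item{members}{tibble `gene_id`, `snp_id` — one row per membership,
#'       SNPs in map order within gene;}
#'     \item{snp_ids}{deduplicated character vector of SNP ids (map
#'       order);}
#'     \item{per_gene_counts}{tibble `gene_id`, `n_snps`, including zero
#'       rows for SNP-less windows;}
#'     \item{n_unique}{number of distinct SNPs in the set.}
#'   }
#' @export
assign_snps <- function(windows, snp_map) {
  stopifnot(is.data.frame(windows),
            all(c("gene_id", "chrom", "win_start", "win_stop") %in%
                  names(windows)),
            is.data.frame(snp_map),
            all(c("snp_id", "chrom", "pos") %in% names(snp_map)))
  if (anyDuplicated(snp_map$snp_id)) {
    stop("duplicate SNP id(s) in the SNP map", call. = FALSE)
  }
  unmatched <- setdiff(unique(windows$chrom), unique(snp_map$chrom))
  if (length(unmatched) && nrow(snp_map)) {
    warning("window chromosome(s) absent from the SNP map: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  snp_map <- dplyr::mutate(snp_map,
                           .ord = dplyr::row_number(),
                           chrom = as.character(.data$chrom))
  members <- windows |>
    dplyr::inner_join(snp_map, by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$win_start,
                  .data$pos <= .data$win_stop) |>
    dplyr::arrange(match(.data$gene_id, windows$gene_id), .data$.ord) |>
    dplyr::select("gene_id", "snp_id")
  counts <- members |>
    dplyr::count(.data$gene_id, name = "n_snps") |>
    dplyr::right_join(tibble::tibble(gene_id = windows$gene_id),
                      by = "gene_id") |>
    dplyr::mutate(n_snps = dplyr::coalesce(.data$n_snps, 0L)) |>
    dplyr::arrange(match(.data$gene_id, windows$gene_id))
  snp_ids <- snp_map$snp_id[sort(unique(match(members$snp_id,
                                              snp_map$snp_id)))]
  structure(list(members = members,
                 snp_ids = snp_ids,
                 per_gene_counts = counts,
                 n_unique = length(snp_ids)),
            class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat(sprintf("<snp_set> %d unique SNP(s) across %d window(s)\n",
              x$n_unique, nrow(x$per_gene_counts)))
  print(x$per_gene_counts, n = 12)
  invisible(x)
}
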