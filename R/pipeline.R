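#' Run the full pathway SNP-set analysis end to end
#'
#' Orchestrates simulate (or load) -> kinship -> windows -> per-SNP mixed
#' model scan -> random-gene-set permutation test -> pleiotropy, and
#' writes every artifact to a run directory: a per-gene table of SNP
#' counts and significant-SNP counts per trait, a per-trait summary table
#' (f-value, experiment-wise P, FDR), pathway and whole-genome effect
#' correlation matrices with their paired-t comparison, the permutation
#' null distributions, one histogram per trait, a machine-readable
#' `summary.json` and a plain-text log.  Re-running with the same inputs
#' and seed reproduces every number exactly.
#'
#' @param sim Either a `pathsnp_sim` object from [simulate_dataset()] or a
#'   [sim_config()] (then the data set is simulated here).
#' @param out_dir Run directory; created if needed.
#' @param flank Window flank in bp.
#' @param alpha Per-SNP significance threshold.
#' @param n_reps Permutation replicates per trait.
#' @param vc_mode `"exact"` or `"null-reuse"`, see [assoc_scan()].
#' @param traits Trait columns to analyse (default: all).
#' @param correct_qtl Optional SNP id whose estimated effect is subtracted
#'   from each phenotype before the scan (known-QTL correction).
#' @param pathway_n_genes,pathway_h2 Passed to [simulate_dataset()] when
#'   `sim` is a config.
#' @param make_plots Write the null-distribution histograms?
#' @param seed Root seed for the permutation stage (default: the
#'   simulation seed).
#' @return An object of class `pathsnp_run`: list with `tests` (one
#'   `pathway_test` per trait), `assoc`, `per_gene_counts`, `summary`,
#'   `pleiotropy`, `out_dir`.
#' @export
run_pipeline <- function(sim, out_dir, flank = 5e5, alpha = 0.05,
                         n_reps = 500L, vc_mode = c("null-reuse", "exact"),
                         traits = NULL, correct_qtl = NULL,
                         pathway_n_genes = 11L, pathway_h2 = 0,
                         make_plots = TRUE, seed = NULL) {
  vc_mode <- match.arg(vc_mode)
  assert_prob(alpha, "alpha")
  if (n_reps < 1) stop("`n_reps` must be at least 1", call. = FALSE)
  t0 <- Sys.time()
  if (inherits(sim, "sim_config")) {
    sim <- simulate_dataset(sim, pathway_n_genes = pathway_n_genes,
                            pathway_h2 = pathway_h2, flank = flank)
  }
  stopifnot(inherits(sim, "pathsnp_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% sim$config$seed
  log_lines <- c(
    sprintf("pathsnpset %s | R %s", utils::packageVersion("pathsnpset"),
            getRversion()),
    sprintf("started %s", format(t0, "%Y-%m-%d %H:%M:%S")),
    sprintf("seed %d, vc_mode %s, alpha %g, flank %d bp, n_reps %d",
            seed, vc_mode, alpha, as.integer(flank), n_reps))

  if (is.null(traits)) {
    traits <- setdiff(
      names(sim$phenotypes)[vapply(sim$phenotypes, is.numeric, logical(1))],
      "animal_id")
  }
  pathway_genes <- dplyr::filter(sim$genes,
                                 .data$gene_id %in% sim$truth$pathway_gene_ids)
  if (!nrow(pathway_genes)) {
    stop("stage windows: the data set declares no pathway genes",
         call. = FALSE)
  }

  phen <- sim$phenotypes
  if (!is.null(correct_qtl)) {
    if (!correct_qtl %in% colnames(sim$genotypes)) {
      stop("stage qtl-correction: SNP ", correct_qtl,
           " is absent from the genotype table", call. = FALSE)
    }
    g <- sim$genotypes[, correct_qtl]
    for (tr in traits) {
      bhat <- test_snp(phen, g, sim$A, mode = vc_mode, trait = tr,
                       snp_id = correct_qtl)$beta
      phen <- correct_phenotype_for_qtl(phen, g, bhat, trait = tr)
      log_lines <- c(log_lines,
                     sprintf("qtl-correction %s (%s): beta_hat = %.6g",
                             correct_qtl, tr, bhat))
    }
  }

  assoc <- assoc_scan(phen, sim$genotypes, sim$A, traits = traits,
                      mode = vc_mode, snp_map = sim$snp_map)
  log_lines <- c(log_lines, sprintf("assoc scan done (%.1f s)",
                                    as.numeric(Sys.time() - t0, "secs")))

  win <- build_windows(pathway_genes, flank = flank)
  sset <- assign_snps(win, sim$snp_map)
  tests <- list()
  null_rows <- list()
  per_gene <- list()
  for (k in seq_along(traits)) {
    tr <- traits[k]
    atr <- dplyr::filter(assoc, .data$trait == tr)
    pt <- pathway_test(atr, pathway_genes, sim$genes, sim$snp_map,
                       flank = flank, alpha = alpha, n_reps = n_reps,
                       seed = stage_seed(seed, "permutation") + k)
    tests[[tr]] <- pt
    null_rows[[tr]] <- tibble::tibble(trait = tr,
                                      replicate = seq_len(n_reps),
                                      proportion = pt$null_proportions)
    sig_ids <- atr$snp_id[!is.na(atr$p_value) & atr$p_value <= alpha]
    per_gene[[tr]] <- sset$members |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(!!paste0("sig_", tr) :=
                         sum(.data$snp_id %in% sig_ids), .groups = "drop")
    log_lines <- c(log_lines,
                   sprintf("permtest %s: f = %.3f, P = %.4f, redraws = %d",
                           tr, pt$proportion_significant,
                           pt$experimentwise_p, pt$redraws))
  }

  per_gene_counts <- purrr::reduce(
    c(list(sset$per_gene_counts), per_gene),
    dplyr::left_join, by = "gene_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("sig_"),
                                ~ dplyr::coalesce(.x, 0L)))

  summary_tbl <- purrr::map_dfr(tests, glance)

  corr_path <- corr_genome <- comparison <- NULL
  if (length(traits) >= 2) {
    corr_path <- effect_correlations(assoc, snp_ids = sset$snp_ids)
    corr_genome <- effect_correlations(assoc)
    # a paired t needs >= 2 trait pairs, i.e. at least 3 traits
    if (length(traits) >= 3) {
      comparison <- paired_t_compare(corr_path, corr_genome)
    }
  }

  # ---- artifacts -----------------------------------------------------
  readr::write_tsv(per_gene_counts, file.path(out_dir, "per_gene_counts.tsv"))
  readr::write_tsv(summary_tbl, file.path(out_dir, "pathway_summary.tsv"))
  readr::write_tsv(dplyr::bind_rows(null_rows),
                   file.path(out_dir, "null_distributions.tsv"))
  readr::write_tsv(assoc, file.path(out_dir, "assoc.tsv"))
  if (!is.null(corr_path)) {
    readr::write_tsv(tidy(corr_path),
                     file.path(out_dir, "correlations_pathway.tsv"))
    readr::write_tsv(tidy(corr_genome),
                     file.path(out_dir, "correlations_genome.tsv"))
    if (!is.null(comparison)) {
      jsonlite::write_json(as.list(comparison),
                           file.path(out_dir, "correlation_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (make_plots) {
    for (tr in traits) {
      ggplot2::ggsave(file.path(out_dir, sprintf("null_hist_%s.png", tr)),
                      autoplot(tests[[tr]]), width = 5, height = 4,
                      dpi = 120)
    }
  }
  summary_json <- list(
    seed = seed, alpha = alpha, flank = flank, n_reps = n_reps,
    vc_mode = vc_mode, n_animals = nrow(sim$pedigree),
    n_snps = ncol(sim$genotypes),
    pathway_genes = pathway_genes$gene_id,
    n_set_snps = sset$n_unique,
    traits = purrr::map(tests, function(pt) list(
      n_snps_tested = pt$n_snps_tested,
      n_significant = pt$n_significant,
      f_value = pt$proportion_significant,
      experimentwise_p = pt$experimentwise_p,
      fdr_percent = pt$fdr_percent,
      redraws = pt$redraws)))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_lines <- c(log_lines, sprintf("finished %.1f s",
                                    as.numeric(Sys.time() - t0, "secs")))
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  structure(list(tests = tests, assoc = assoc,
                 per_gene_counts = per_gene_counts,
                 summary = summary_tbl,
                 pleiotropy = list(pathway = corr_path,
                                   genome = corr_genome,
                                   comparison = comparison),
                 snp_set = sset, out_dir = out_dir),
            class = "pathsnp_run")
}

#' @export
print.pathsnp_run <- function(x, ...) {
  cat("<pathsnp_run>", x$out_dir, "\n")
  print(dplyr::select(x$summary, "trait", "n_snps_tested", "n_significant",
                      "proportion_significant", "experimentwise_p",
                      "fdr_percent"))
  invisible(x)
}
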