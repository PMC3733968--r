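#' Correlations of per-SNP effects across traits
#'
#' Pleiotropy proxy: the Pearson correlation between the per-SNP effect
#' estimates of every pair of traits over a common SNP set.  The
#' `selection_rule` decides which SNPs enter each pair:
#' `"all"` uses every SNP; `"significant-any"` keeps SNPs with
#' `p <= alpha` in at least one trait of the pair; `"significant-both"`
#' requires it in both.  Pairs left with fewer than 3 SNPs are flagged
#' missing.
#'
#' @param assoc Long association tibble with columns `trait`, `snp_id`,
#'   `beta`, `p_value`; all traits must cover the same SNP set.
#' @param snp_ids Optional SNP ids restricting the set (e.g. a pathway SNP
#'   set); default: all SNPs present.
#' @param selection_rule `"all"`, `"significant-any"` or
#'   `"significant-both"`.
#' @param alpha Threshold used by the significance rules.
#' @return An object of class `effect_corr`: list with `correlations`
#'   (trait x trait matrix), `n_snps` (matrix of per-pair SNP counts),
#'   `trait_names`, `selection_rule`, `alpha`.
#' @export
effect_correlations <- function(assoc, snp_ids = NULL,
                                selection_rule = c("all", "significant-any",
                                                   "significant-both"),
                                alpha = 0.05) {
  selection_rule <- match.arg(selection_rule)
  stopifnot(all(c("trait", "snp_id", "beta", "p_value") %in% names(assoc)))
  if (!is.null(snp_ids)) {
    assoc <- dplyr::filter(assoc, .data$snp_id %in% snp_ids)
  }
  assoc <- dplyr::filter(assoc, !is.na(.data$beta))
  traits <- unique(assoc$trait)
  if (length(traits) < 2) stop("need at least two traits", call. = FALSE)
  wide_b <- assoc |>
    dplyr::select("trait", "snp_id", "beta") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "beta")
  wide_p <- assoc |>
    dplyr::select("trait", "snp_id", "p_value") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "p_value")
  B <- as.matrix(wide_b[traits])
  P <- as.matrix(wide_p[traits])
  nt <- length(traits)
  corr <- diag(1, nt)
  nmat <- matrix(nrow(B), nt, nt)
  dimnames(corr) <- dimnames(nmat) <- list(traits, traits)
  for (i in seq_len(nt - 1)) {
    for (j in seq(i + 1, nt)) {
      keep <- switch(selection_rule,
        "all" = rep(TRUE, nrow(B)),
        "significant-any" = P[, i] <= alpha | P[, j] <= alpha,
        "significant-both" = P[, i] <= alpha & P[, j] <= alpha)
      keep <- keep & !is.na(B[, i]) & !is.na(B[, j])
      nmat[i, j] <- nmat[j, i] <- sum(keep)
      if (sum(keep) < 3) {
        corr[i, j] <- corr[j, i] <- NA_real_
      } else {
        corr[i, j] <- corr[j, i] <- stats::cor(B[keep, i], B[keep, j])
      }
    }
  }
  structure(list(correlations = corr, n_snps = nmat, trait_names = traits,
                 selection_rule = selection_rule, alpha = alpha),
            class = "effect_corr")
}

#' @export
print.effect_corr <- function(x, ...) {
  cat(sprintf("<effect_corr> rule '%s' (alpha = %g)\n",
              x$selection_rule, x$alpha))
  print(round(x$correlations, 3))
  invisible(x)
}

#' Paired t-test between two correlation sets
#'
#' Compares two effect-correlation matrices over the same trait panel
#' (e.g. a pathway SNP set versus the whole genome) by a paired t-test on
#' the unique off-diagonal entries (15 pairs for 6 traits):
#' `t = mean(d) / (sd(d)/sqrt(k))`, `df = k - 1`, two-sided.  All-zero
#' differences return `t = 0, p = 1`.
#'
#' @param corr_a,corr_b `effect_corr` objects with identical trait panels.
#' @return A one-row tibble: `t_stat`, `df`, `p_value`, `n_pairs`,
#'   `mean_difference`.
#' @export
paired_t_compare <- function(corr_a, corr_b) {
  stopifnot(inherits(corr_a, "effect_corr"), inherits(corr_b, "effect_corr"))
  if (!identical(corr_a$trait_names, corr_b$trait_names)) {
    stop("the two correlation sets cover different trait panels",
         call. = FALSE)
  }
  lower <- lower.tri(corr_a$correlations)
  d <- corr_a$correlations[lower] - corr_b$correlations[lower]
  d <- d[!is.na(d)]
  k <- length(d)
  if (k < 2) stop("need at least two correlation pairs", call. = FALSE)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(k))
  }
  p <- if (is.infinite(t_stat)) 0 else
    2 * stats::pt(abs(t_stat), df = k - 1, lower.tail = FALSE)
  if (t_stat == 0) p <- 1
  tibble::tibble(t_stat = t_stat, df = k - 1, p_value = p, n_pairs = k,
                 mean_difference = mean(d))
}
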