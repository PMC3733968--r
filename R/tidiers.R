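#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pathway test
#'
#' One row per permutation replicate with the replicate's null proportion,
#' plus the observed statistic carried alongside.
#'
#' @param x A `pathway_test` object.
#' @param ... Unused.
#' @return A tibble `replicate`, `null_proportion`, `observed`.
#' @method tidy pathway_test
#' @export
tidy.pathway_test <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_proportions),
                 null_proportion = x$null_proportions,
                 observed = x$proportion_significant)
}

#' One-row summary of a pathway test
#'
#' @inheritParams tidy.pathway_test
#' @return A one-row tibble with the observed counts, proportion,
#'   experiment-wise P and FDR.
#' @method glance pathway_test
#' @export
glance.pathway_test <- function(x, ...) {
  tibble::tibble(trait = x$trait,
                 n_snps_tested = x$n_snps_tested,
                 n_significant = x$n_significant,
                 proportion_significant = x$proportion_significant,
                 alpha = x$alpha,
                 experimentwise_p = x$experimentwise_p,
                 fdr_percent = x$fdr_percent,
                 fdr_raw_percent = x$fdr_raw_percent,
                 n_reps = x$n_reps,
                 seed = x$seed)
}

#' Tidy a variance-component fit
#'
#' @param x A `vc_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per component (`sigma_a2`, `sigma_e2`).
#' @method tidy vc_fit
#' @export
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(component = c("sigma_a2", "sigma_e2"),
                 estimate = c(x$sigma_a2, x$sigma_e2))
}

#' One-row summary of a variance-component fit
#'
#' @inheritParams tidy.vc_fit
#' @return A one-row tibble: `trait`, `sigma_a2`, `sigma_e2`, `h2`,
#'   `delta`, `loglik_reml`, `n`.
#' @method glance vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, sigma_a2 = x$sigma_a2,
                 sigma_e2 = x$sigma_e2, h2 = x$h2, delta = x$delta,
                 loglik_reml = x$loglik_reml, n = x$n)
}

#' Tidy an effect-correlation matrix
#'
#' @param x An `effect_corr` object.
#' @param ... Unused.
#' @return A tibble with one row per unique trait pair: `trait_a`,
#'   `trait_b`, `correlation`, `n_snps`.
#' @method tidy effect_corr
#' @export
tidy.effect_corr <- function(x, ...) {
  traits <- x$trait_names
  idx <- which(lower.tri(x$correlations), arr.ind = TRUE)
  tibble::tibble(trait_a = traits[idx[, 2]],
                 trait_b = traits[idx[, 1]],
                 correlation = x$correlations[idx],
                 n_snps = x$n_snps[idx])
}
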