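#' @title Per-SNP pedigree mixed model
#' @description
#' The association model for one trait and one SNP is
#' \deqn{y = 1_n\mu + x\beta + u + e, \quad u \sim N(0, A\sigma^2_a),
#'       \quad e \sim N(0, I\sigma^2_e),}
#' with \eqn{A} the pedigree numerator relationship matrix.  Writing
#' \eqn{\delta = \sigma^2_e/\sigma^2_a}, the covariance is
#' \eqn{V = \sigma^2_a (A + \delta I)}; a single spectral decomposition
#' \eqn{A = U D U'} rotates the model to independent observations with
#' weights \eqn{1/(d_i + \delta)}, so the restricted likelihood is a cheap
#' one-dimensional function of \eqn{\delta} and each SNP test is a weighted
#' 2x2 GLS solve.
#' @name mixed_model
NULL

#' Cache the spectral decomposition of a kinship matrix
#'
#' @param A Symmetric PSD relationship matrix with animal ids as dimnames.
#' @return An object of class `kinship_eigen` (ids, eigenvalues clipped at
#'   zero, rotation matrix).
#' @export
kinship_eigen <- function(A) {
  if (inherits(A, "kinship_eigen")) return(A)
  stopifnot(is.matrix(A), nrow(A) == ncol(A), !is.null(rownames(A)))
  es <- eigen(A, symmetric = TRUE)
  structure(list(ids = rownames(A),
                 values = pmax(es$values, 0),
                 vectors = es$vectors),
            class = "kinship_eigen")
}

# Profile restricted log-likelihood at ratio delta = sigma_e2 / sigma_a2,
# on rotated data (yr = U'y, Xr = U'X, d = eigenvalues of A).  Returns the
# full REML log-likelihood (constants included) plus the profiled
# components and the GLS solution.
.reml_profile <- function(yr, Xr, d, delta) {
  n <- length(yr)
  p <- ncol(Xr)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xr, Xr * w)
  XtWy <- crossprod(Xr, yr * w)
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) {
    return(list(loglik = -Inf, beta = rep(NA_real_, p), cov_unscaled = NULL,
                sigma_a2 = NA_real_, sigma_e2 = NA_real_))
  }
  beta <- backsolve(R, backsolve(R, XtWy, transpose = TRUE))
  r <- yr - Xr %*% beta
  rss <- sum(w * r^2)
  sigma_a2 <- rss / (n - p)
  loglik <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma_a2) +
                      sum(log(d + delta)) + 2 * sum(log(diag(R))) + (n - p))
  list(loglik = loglik, beta = drop(beta), chol_XtWX = R,
       sigma_a2 = sigma_a2, sigma_e2 = sigma_a2 * delta, rss = rss)
}

# Maximize the restricted likelihood over log(delta) in [log lo, log hi].
.reml_optimize <- function(yr, Xr, d, lo = 1e-6, hi = 1e6, tol = 1e-8) {
  obj <- function(ld) -.reml_profile(yr, Xr, d, exp(ld))$loglik
  opt <- stats::optimize(obj, c(log(lo), log(hi)), tol = tol)
  # guard against a better value sitting on either boundary
  cand <- c(opt$minimum, log(lo), log(hi))
  vals <- c(opt$objective, obj(log(lo)), obj(log(hi)))
  ld <- cand[which.min(vals)]
  fit <- .reml_profile(yr, Xr, d, exp(ld))
  fit$delta <- exp(ld)
  fit
}

#' Estimate REML variance components under the polygenic model
#'
#' Maximizes the restricted likelihood of `y = X b + u + e`,
#' `u ~ N(0, A sigma_a2)`, over the variance ratio
#' `delta = sigma_e2 / sigma_a2` (searched on a log scale over
#' `[1e-6, 1e6]`, which covers both boundary regimes), using one spectral
#' decomposition of `A`.
#'
#' @param phenotypes Data frame with an `animal_id` column and one column
#'   per trait.
#' @param A Relationship matrix from [kinship_matrix()], or a cached
#'   [kinship_eigen()] object.
#' @param trait Name of the trait column to analyse; default: the first
#'   non-id numeric column.
#' @param covariates Optional numeric matrix of extra fixed effects (rows
#'   aligned to `phenotypes`); an intercept is always included.
#' @return An object of class `vc_fit`: `sigma_a2`, `sigma_e2`, `delta`,
#'   `h2`, `loglik_reml`, `n`, `trait`.
#' @export
#' @examples
#' ped <- simulate_pedigree(sim_config(n_founders = 30, n_generations = 4,
#'                                     n_animals = 150, seed = 2))
#' A <- kinship_matrix(ped)
#' cfg <- sim_config(n_founders = 30, n_generations = 4, n_animals = 150,
#'                   n_traits = 1, sigma_a2 = 0.5, sigma_e2 = 0.5, seed = 2)
#' y <- simulate_traits(ped, NULL, A, cfg)
#' fit <- estimate_variance_components(y, A)
#' fit$h2
estimate_variance_components <- function(phenotypes, A, trait = NULL,
                                         covariates = NULL) {
  dat <- .align_pheno(phenotypes, A, trait)
  if (dat$n < 3) stop("need at least 3 animals", call. = FALSE)
  X <- cbind(intercept = rep(1, dat$n), covariates)
  yr <- crossprod(dat$eig$vectors, dat$y)
  Xr <- crossprod(dat$eig$vectors, X)
  fit <- .reml_optimize(yr, Xr, dat$eig$values)
  structure(list(sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
                 delta = fit$delta,
                 h2 = fit$sigma_a2 / (fit$sigma_a2 + fit$sigma_e2),
                 loglik_reml = fit$loglik, n = dat$n, trait = dat$trait),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf(
    "<vc_fit> trait %s: sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f (n = %d)\n",
    x$trait, x$sigma_a2, x$sigma_e2, x$h2, x$n))
  invisible(x)
}

# Align a phenotype data frame with the kinship ids; returns rotated pieces.
.align_pheno <- function(phenotypes, A, trait = NULL) {
  stopifnot(is.data.frame(phenotypes), "animal_id" %in% names(phenotypes))
  if (is.null(trait)) {
    num <- names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))]
    trait <- setdiff(num, "animal_id")[1]
  }
  y <- phenotypes[[trait]]
  if (!is.numeric(y)) stop("trait column must be numeric", call. = FALSE)
  ids <- as.character(phenotypes$animal_id)
  keep <- is.finite(y)
  if (!all(keep)) {
    y <- y[keep]
    ids <- ids[keep]
  }
  eig <- kinship_eigen(A)
  if (!all(ids %in% eig$ids)) {
    stop("phenotyped animal(s) missing from the relationship matrix",
         call. = FALSE)
  }
  if (!identical(ids, eig$ids)) {
    # sub-setting invalidates a cached decomposition: rebuild on the subset
    if (inherits(A, "kinship_eigen")) {
      stop("pass the raw A matrix when phenotype ids differ from its ids",
           call. = FALSE)
    }
    eig <- kinship_eigen(A[ids, ids, drop = FALSE])
  }
  list(y = y, ids = ids, eig = eig, n = length(y), trait = trait)
}

#' Test one SNP under the pedigree mixed model
#'
#' Fits `y = mu + x beta + u + e` and reports the GLS estimate of the
#' per-allele SNP effect, its standard error, the 1-df Wald
#' `F = (beta/se)^2`, and the p-value from an `F(1, n - p)` reference
#' (`p` = number of fixed effects, here 2).  With `mode = "exact"` the
#' variance components are re-estimated by REML with the SNP in the fixed
#' design (per-SNP REML); `mode = "null-reuse"` reuses components
#' estimated once without the SNP (EMMAX-style).  Animals with a missing
#' genotype are dropped for that SNP.
#'
#' @inheritParams estimate_variance_components
#' @param x Genotype vector (0/1/2 allele counts), aligned to
#'   `phenotypes$animal_id` (or named by animal id).
#' @param mode `"exact"` or `"null-reuse"`.
#' @param vc Optional list/`vc_fit` with `sigma_a2`, `sigma_e2` to hold the
#'   variance components fixed (e.g. `sigma_a2 = 0` reduces the test to
#'   ordinary least squares).  Overrides `mode`.
#' @param snp_id Label recorded in the result.
#' @return A one-row tibble: `snp_id`, `n_used`, `beta`, `se`, `f_stat`,
#'   `p_value`, `sigma_a2`, `sigma_e2`, `monomorphic`.
#' @export
test_snp <- function(phenotypes, x, A, mode = c("exact", "null-reuse"),
                     vc = NULL, trait = NULL, snp_id = "snp") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(phenotypes), "animal_id" %in% names(phenotypes))
  ids0 <- as.character(phenotypes$animal_id)
  if (!is.null(names(x))) x <- x[ids0]
  if (length(x) != nrow(phenotypes)) {
    stop("genotype vector is not aligned to the phenotypes", call. = FALSE)
  }
  keep <- !is.na(x)
  ph <- phenotypes[keep, , drop = FALSE]
  x <- as.numeric(x[keep])
  dat <- .align_pheno(ph, A, trait)
  x <- x[is.finite(ph[[dat$trait]])]

  mono_row <- function(n_used) tibble::tibble(
    snp_id = snp_id, n_used = n_used, beta = NA_real_, se = NA_real_,
    f_stat = NA_real_, p_value = NA_real_, sigma_a2 = NA_real_,
    sigma_e2 = NA_real_, monomorphic = TRUE)
  if (stats::var(x) == 0) return(mono_row(dat$n))

  X <- cbind(1, x)
  if (!is.null(vc)) {
    sa <- vc$sigma_a2
    se2 <- vc$sigma_e2
    if (sa == 0) {
      # V proportional to I: plain weighted solve with unit weights
      fit <- .reml_profile(dat$y, X, rep(0, dat$n), delta = 1)
      cov_b <- fit$sigma_a2 * chol2inv(fit$chol_XtWX)
    } else {
      yr <- crossprod(dat$eig$vectors, dat$y)
      Xr <- crossprod(dat$eig$vectors, X)
      fit <- .reml_profile(yr, Xr, dat$eig$values, delta = se2 / sa)
      cov_b <- fit$sigma_a2 * chol2inv(fit$chol_XtWX)
    }
  } else {
    yr <- crossprod(dat$eig$vectors, dat$y)
    Xr <- crossprod(dat$eig$vectors, X)
    if (mode == "exact") {
      fit <- .reml_optimize(yr, Xr, dat$eig$values)
    } else {
      null_fit <- .reml_optimize(yr, Xr[, 1, drop = FALSE], dat$eig$values)
      fit <- .reml_profile(yr, Xr, dat$eig$values, delta = null_fit$delta)
    }
    cov_b <- fit$sigma_a2 * chol2inv(fit$chol_XtWX)
  }
  beta <- fit$beta[2]
  se_b <- sqrt(cov_b[2, 2])
  f <- (beta / se_b)^2
  tibble::tibble(snp_id = snp_id, n_used = dat$n, beta = beta, se = se_b,
                 f_stat = f,
                 p_value = stats::pf(f, 1, dat$n - 2, lower.tail = FALSE),
                 sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
                 monomorphic = FALSE)
}

#' Genome scan: test every SNP for one or more traits
#'
#' Runs [test_snp()] over the columns of a genotype matrix.  In
#' `"null-reuse"` mode the variance ratio is estimated once per trait
#' without any SNP and every SNP test is a vectorized weighted 2x2 GLS
#' solve; in `"exact"` mode the ratio is re-optimized per SNP (both share
#' one spectral decomposition of `A`).  SNPs with missing genotypes fall
#' back to the per-SNP complete-case path.
#'
#' @inheritParams estimate_variance_components
#' @param genotypes Animal x SNP matrix of 0/1/2 counts with ids as
#'   rownames.
#' @param traits Character vector of trait columns (default: all numeric
#'   columns).
#' @param mode `"exact"` (per-SNP REML, the default) or `"null-reuse"`.
#' @param snp_map Optional SNP map; when given, `chrom` and `pos` are
#'   joined onto the result.
#' @return A tibble with one row per SNP x trait: `trait`, `snp_id`,
#'   (`chrom`, `pos`,) `n_used`, `beta`, `se`, `f_stat`, `p_value`,
#'   `monomorphic`.
#' @export
assoc_scan <- function(phenotypes, genotypes, A,
                       traits = NULL, mode = c("exact", "null-reuse"),
                       snp_map = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(genotypes), !is.null(rownames(genotypes)))
  if (is.null(traits)) {
    traits <- setdiff(
      names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))],
      "animal_id")
  }
  out <- purrr::map(traits, function(tr) {
    dat <- .align_pheno(phenotypes, A, tr)
    G <- genotypes[dat$ids, , drop = FALSE]
    n <- dat$n
    complete <- colSums(is.na(G)) == 0
    yr <- crossprod(dat$eig$vectors, dat$y)
    Gr <- crossprod(dat$eig$vectors, G[, complete, drop = FALSE])
    onr <- crossprod(dat$eig$vectors, rep(1, n))
    d <- dat$eig$values
    mono <- apply(G[, complete, drop = FALSE], 2,
                  function(g) stats::var(g) == 0)

    if (mode == "null-reuse") {
      nf <- .reml_optimize(yr, onr, d)
      res <- .gls_scan(yr, onr, Gr, d, nf$delta)
    } else {
      res <- .exact_scan(yr, onr, Gr, d, skip = mono)
    }
    res$snp_id <- colnames(Gr)
    res$n_used <- n
    res$monomorphic <- unname(mono)
    res[mono, c("beta", "se", "f_stat", "p_value")] <- NA_real_

    miss <- colnames(G)[!complete]
    if (length(miss)) {
      extra <- purrr::map_dfr(miss, function(s) {
        test_snp(phenotypes, G[, s], A, mode = mode, trait = tr, snp_id = s)
      })
      res <- dplyr::bind_rows(
        res, dplyr::select(extra, "snp_id", "n_used", "beta", "se",
                           "f_stat", "p_value", "monomorphic"))
    }
    res$trait <- tr
    res
  })
  res <- dplyr::bind_rows(out)
  res <- dplyr::select(res, "trait", "snp_id", "n_used", "beta", "se",
                       "f_stat", "p_value", "monomorphic")
  if (!is.null(snp_map)) {
    res <- dplyr::left_join(res, snp_map, by = "snp_id") |>
      dplyr::relocate("chrom", "pos", .after = "snp_id")
  }
  # keep SNPs in genotype-column order within trait
  res <- dplyr::arrange(res, match(.data$trait, traits),
                        match(.data$snp_id, colnames(genotypes)))
  tibble::as_tibble(res)
}

# Vectorized weighted GLS of y on [1, x_j] for all SNP columns at a fixed
# variance ratio.
.gls_scan <- function(yr, onr, Gr, d, delta) {
  n <- length(yr)
  w <- 1 / (d + delta)
  a11 <- sum(w * onr^2)
  a12 <- drop(crossprod(Gr, w * onr))
  a22 <- colSums(Gr^2 * w)
  b1 <- sum(w * onr * yr)
  b2 <- drop(crossprod(Gr, w * yr))
  yy <- sum(w * yr^2)
  det <- a11 * a22 - a12^2
  beta <- (a11 * b2 - a12 * b1) / det
  mu <- (a22 * b1 - a12 * b2) / det
  rss <- yy - mu * b1 - beta * b2
  sigma_a2 <- rss / (n - 2)
  var_b <- sigma_a2 * a11 / det
  se <- sqrt(pmax(var_b, 0))
  f <- (beta / se)^2
  tibble::tibble(beta = beta, se = se, f_stat = f,
                 p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# Per-SNP REML: re-optimize the variance ratio with the SNP in the design.
.exact_scan <- function(yr, onr, Gr, d, skip = NULL) {
  m <- ncol(Gr)
  beta <- se <- rep(NA_real_, m)
  n <- length(yr)
  for (j in seq_len(m)) {
    if (!is.null(skip) && skip[j]) next
    X <- cbind(onr, Gr[, j])
    fit <- .reml_optimize(yr, X, d)
    cov_b <- fit$sigma_a2 * chol2inv(fit$chol_XtWX)
    beta[j] <- fit$beta[2]
    se[j] <- sqrt(cov_b[2, 2])
  }
  f <- (beta / se)^2
  tibble::tibble(beta = beta, se = se, f_stat = f,
                 p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

#' Subtract a known QTL effect from phenotypes
#'
#' Re-expresses each animal's phenotype with the effect of a known
#' large-effect QTL removed: `y_i' = y_i - g_i * beta_hat`, where `g_i` is
#' the animal's allele count at the QTL SNP and `beta_hat` the per-allele
#' effect estimated from the association scan.  Used to check that a
#' pathway signal is not driven by a neighbouring major gene (the DGAT1
#' situation).  Animals with a missing QTL genotype get a missing
#' phenotype (dropped downstream) with a warning.
#'
#' @param phenotypes Data frame with `animal_id` and trait columns.
#' @param g QTL genotype vector (0/1/2), aligned to `phenotypes` or named
#'   by animal id.
#' @param beta_hat Estimated per-allele effect to subtract.
#' @param trait Trait column to correct (default: first numeric column).
#' @return The phenotype tibble with the corrected trait column; other
#'   columns untouched.
#' @export
correct_phenotype_for_qtl <- function(phenotypes, g, beta_hat,
                                      trait = NULL) {
  stopifnot(is.data.frame(phenotypes), "animal_id" %in% names(phenotypes),
            is.finite(beta_hat))
  if (is.null(trait)) {
    trait <- setdiff(
      names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))],
      "animal_id")[1]
  }
  if (!is.null(names(g))) g <- g[as.character(phenotypes$animal_id)]
  if (length(g) != nrow(phenotypes)) {
    stop("QTL genotype vector is not aligned to the phenotypes",
         call. = FALSE)
  }
  if (anyNA(g)) {
    warning(sum(is.na(g)),
            " animal(s) lack the QTL genotype; their corrected phenotype ",
            "is set to missing", call. = FALSE)
  }
  phenotypes[[trait]] <- phenotypes[[trait]] - as.numeric(g) * beta_hat
  tibble::as_tibble(phenotypes)
}
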