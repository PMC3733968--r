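# Shared 50-animal fixture with a non-trivial pedigree.
mm_fixture <- function(seed = 50) {
  cfg <- test_config(n_founders = 15, n_generations = 3, n_animals = 50,
                     n_chromosomes = 1, n_snps = 30, n_traits = 1,
                     sigma_a2 = 0.4, sigma_e2 = 0.6, seed = seed)
  ped <- simulate_pedigree(cfg)
  A <- kinship_matrix(ped)
  g <- simulate_genotypes(ped, cfg)$genotypes
  y <- simulate_traits(ped, g, A, cfg)
  list(ped = ped, A = A, g = g, y = y, cfg = cfg)
}

test_that("with sigma_a2 = 0 the SNP test is exactly ordinary least squares", {
  fx <- mm_fixture()
  x <- fx$g[, 3]
  res <- test_snp(fx$y, x, fx$A, vc = list(sigma_a2 = 0, sigma_e2 = 1))
  ols <- summary(stats::lm(fx$y$trait_1 ~ x))$coefficients
  expect_equal(res$beta, ols["x", "Estimate"], tolerance = 1e-10)
  expect_equal(res$se, ols["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(res$p_value, ols["x", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("beta, se and p match a dense GLS oracle at fixed components", {
  fx <- mm_fixture()
  sa <- 0.35
  se2 <- 0.65
  V <- sa * fx$A + se2 * diag(nrow(fx$A))
  for (j in c(2, 7, 15)) {
    x <- fx$g[, j]
    res <- test_snp(fx$y, x, fx$A, vc = list(sigma_a2 = sa, sigma_e2 = se2))
    orc <- dense_gls(fx$y$trait_1, x, V)
    expect_equal(res$beta, orc$beta, tolerance = 1e-8)
    expect_equal(res$se, orc$se, tolerance = 1e-8)
    expect_equal(res$p_value, orc$p, tolerance = 1e-8)
  }
})

test_that("REML optimum beats a 40-point dense-matrix grid oracle", {
  fx <- mm_fixture()
  fit <- estimate_variance_components(fx$y, fx$A)
  X <- matrix(1, nrow(fx$A), 1)
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 40))
  ll_grid <- vapply(grid, function(d) {
    dense_reml_loglik(fx$y$trait_1, X, fx$A, d)
  }, numeric(1))
  expect_gte(fit$loglik_reml, max(ll_grid) - 1e-6)
  # and the package loglik agrees with the dense formula at the optimum
  expect_equal(fit$loglik_reml,
               dense_reml_loglik(fx$y$trait_1, X, fx$A, fit$delta),
               tolerance = 1e-6)
})

test_that("variance components are scale-equivariant", {
  fx <- mm_fixture()
  f1 <- estimate_variance_components(fx$y, fx$A)
  y3 <- fx$y
  y3$trait_1 <- 3 * y3$trait_1
  f9 <- estimate_variance_components(y3, fx$A)
  expect_equal(f9$sigma_a2, 9 * f1$sigma_a2, tolerance = 1e-4)
  expect_equal(f9$sigma_e2, 9 * f1$sigma_e2, tolerance = 1e-4)
  expect_equal(f9$delta, f1$delta, tolerance = 1e-4)
})

test_that("pure-residual simulations give near-zero heritability estimates", {
  h2 <- vapply(1:20, function(s) {
    cfg <- test_config(n_founders = 60, n_generations = 4, n_animals = 400,
                       n_traits = 1, sigma_a2 = 0, sigma_e2 = 1, seed = s)
    ped <- simulate_pedigree(cfg)
    A <- kinship_matrix(ped)
    y <- simulate_traits(ped, NULL, A, cfg)
    estimate_variance_components(y, A)$h2
  }, numeric(1))
  expect_lt(mean(h2), 0.1)
})

test_that("monomorphic SNPs are flagged and excluded from testing", {
  fx <- mm_fixture()
  x <- rep(2, nrow(fx$y))
  res <- test_snp(fx$y, x, fx$A)
  expect_true(res$monomorphic)
  expect_true(is.na(res$p_value))
})

test_that("p-values are invariant to affine phenotype rescaling and allele flip", {
  fx <- mm_fixture()
  x <- fx$g[, 9]
  r1 <- test_snp(fx$y, x, fx$A, mode = "exact")
  y2 <- fx$y
  y2$trait_1 <- -2 * y2$trait_1 + 7
  r2 <- test_snp(y2, x, fx$A, mode = "exact")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-6)
  r3 <- test_snp(fx$y, 2 - x, fx$A, mode = "exact")
  expect_equal(r3$beta, -r1$beta, tolerance = 1e-6)
  expect_equal(r3$p_value, r1$p_value, tolerance = 1e-6)
})

test_that("missing genotypes trigger complete-case analysis", {
  fx <- mm_fixture()
  x <- fx$g[, 4]
  x[c(1, 5, 9)] <- NA
  res <- test_snp(fx$y, x, fx$A, mode = "exact")
  expect_equal(res$n_used, nrow(fx$y) - 3)
  keep <- !is.na(x)
  res2 <- test_snp(fx$y[keep, ], x[keep],
                   fx$A[as.character(fx$y$animal_id[keep]),
                        as.character(fx$y$animal_id[keep])],
                   mode = "exact")
  expect_equal(res$beta, res2$beta, tolerance = 1e-10)
})

test_that("null-reuse and exact modes agree closely for small effects", {
  cfg <- test_config(n_founders = 80, n_generations = 3, n_animals = 300,
                     n_chromosomes = 2, n_snps = 100, n_traits = 1,
                     sigma_a2 = 0.3, sigma_e2 = 0.7, seed = 77)
  ped <- simulate_pedigree(cfg)
  A <- kinship_matrix(ped)
  g <- simulate_genotypes(ped, cfg)$genotypes
  y <- simulate_traits(ped, g, A, cfg)
  scan_e <- assoc_scan(y, g, A, mode = "exact")
  scan_n <- assoc_scan(y, g, A, mode = "null-reuse")
  ok <- !scan_e$monomorphic
  d <- abs(scan_e$p_value[ok] - scan_n$p_value[ok])
  # typical agreement is well below 0.01; individual SNPs in LD with the
  # polygenic background can shift delta and differ by a few times that
  expect_lt(mean(d), 0.01)
  expect_lt(stats::median(d), 0.01)
  expect_gt(stats::cor(scan_e$beta[ok], scan_n$beta[ok]), 0.999)
})

test_that("assoc_scan matches test_snp row by row", {
  fx <- mm_fixture(seed = 3)
  scan <- assoc_scan(fx$y, fx$g[, 1:8], fx$A, mode = "exact",
                     snp_map = NULL)
  for (j in c(1, 4, 8)) {
    one <- test_snp(fx$y, fx$g[, j], fx$A, mode = "exact",
                    snp_id = colnames(fx$g)[j])
    row <- scan[scan$snp_id == colnames(fx$g)[j], ]
    expect_equal(row$beta, one$beta, tolerance = 1e-6)
    expect_equal(row$p_value, one$p_value, tolerance = 1e-6)
  }
})

test_that("QTL correction subtracts g * beta and preserves other columns", {
  fx <- mm_fixture()
  g <- fx$g[, 1]
  y0 <- fx$y
  y1 <- correct_phenotype_for_qtl(y0, g, beta_hat = 0)
  expect_equal(y1, y0)
  y2 <- correct_phenotype_for_qtl(y0, rep(0, nrow(y0)), beta_hat = 1.3)
  expect_equal(y2, y0)
  y3 <- correct_phenotype_for_qtl(y0, g, beta_hat = 0.8)
  expect_equal(y3$trait_1, y0$trait_1 - 0.8 * unname(g))
  gna <- g
  gna[2] <- NA
  expect_warning(y4 <- correct_phenotype_for_qtl(y0, gna, 0.5), "missing")
  expect_true(is.na(y4$trait_1[2]))
})

test_that("correcting an estimated QTL removes its re-tested signal", {
  cfg <- test_config(n_founders = 80, n_generations = 3, n_animals = 300,
                     n_chromosomes = 1, n_snps = 60, n_traits = 1,
                     sigma_a2 = 0.3, sigma_e2 = 0.7, seed = 61)
  ped <- simulate_pedigree(cfg)
  A <- kinship_matrix(ped)
  g <- simulate_genotypes(ped, cfg)$genotypes
  qtl <- colnames(g)[30]
  cfg$pathway_effect_sizes <- stats::setNames(list(0.8), qtl)
  y <- simulate_traits(ped, g, A, cfg)
  est <- test_snp(y, g[, qtl], A, mode = "exact")
  expect_gt(abs(est$beta / est$se), 2)  # the QTL is detectable
  ycorr <- correct_phenotype_for_qtl(y, g[, qtl], est$beta)
  re <- test_snp(ycorr, g[, qtl], A, mode = "exact")
  expect_lt(abs(re$beta), 2 * re$se)
})
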