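make_assoc <- function(betas, pvals = NULL) {
  traits <- names(betas)
  n <- length(betas[[1]])
  purrr::map_dfr(traits, function(tr) {
    tibble::tibble(trait = tr, snp_id = paste0("s", seq_len(n)),
                   beta = betas[[tr]],
                   p_value = if (is.null(pvals)) rep(0.5, n) else
                     pvals[[tr]])
  })
}

test_that("perfect correlation and anticorrelation are recovered", {
  assoc <- make_assoc(list(a = c(1, 2, 3, 4), b = c(-1, -2, -3, -4),
                           c = c(2, 4, 6, 8)))
  ec <- effect_correlations(assoc)
  expect_equal(ec$correlations["a", "b"], -1)
  expect_equal(ec$correlations["a", "c"], 1)
  expect_equal(unname(diag(ec$correlations)), rep(1, 3))
  expect_true(isSymmetric(ec$correlations))
})

test_that("correlations match a hand-computed Pearson formula", {
  set.seed(8)
  b1 <- stats::rnorm(8)
  b2 <- 0.5 * b1 + stats::rnorm(8)
  assoc <- make_assoc(list(x = b1, y = b2))
  ec <- effect_correlations(assoc)
  manual <- sum((b1 - mean(b1)) * (b2 - mean(b2))) /
    sqrt(sum((b1 - mean(b1))^2) * sum((b2 - mean(b2))^2))
  expect_equal(ec$correlations["x", "y"], manual, tolerance = 1e-12)
  expect_equal(ec$n_snps["x", "y"], 8)
})

test_that("selection rules filter SNP pairs as documented", {
  pv <- list(x = c(0.01, 0.5, 0.01, 0.9), y = c(0.5, 0.01, 0.01, 0.9))
  bb <- list(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  assoc <- make_assoc(bb, pv)
  any_rule <- effect_correlations(assoc, selection_rule = "significant-any")
  expect_equal(any_rule$n_snps["x", "y"], 3)
  both_rule <- effect_correlations(assoc, selection_rule = "significant-both")
  expect_true(is.na(both_rule$correlations["x", "y"]))  # only 1 SNP left
  expect_equal(both_rule$n_snps["x", "y"], 1)
})

test_that("correlations are invariant to rescaling one trait's effects", {
  set.seed(12)
  assoc <- make_assoc(list(x = stats::rnorm(20), y = stats::rnorm(20)))
  ec1 <- effect_correlations(assoc)
  assoc2 <- dplyr::mutate(assoc, beta = ifelse(trait == "x",
                                               10 * beta, beta))
  ec2 <- effect_correlations(assoc2)
  expect_equal(ec1$correlations, ec2$correlations, tolerance = 1e-12)
})

test_that("identical correlation sets compare as t = 0, p = 1", {
  set.seed(3)
  assoc <- make_assoc(list(x = stats::rnorm(10), y = stats::rnorm(10),
                           z = stats::rnorm(10)))
  ec <- effect_correlations(assoc)
  cmp <- paired_t_compare(ec, ec)
  expect_equal(cmp$t_stat, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$n_pairs, 3)
})

test_that("a consistent shift between correlation sets is detected", {
  traits <- c("a", "b", "c", "d")
  k <- 6
  set.seed(21)
  base <- matrix(0.3, 4, 4, dimnames = list(traits, traits))
  diag(base) <- 1
  shifted <- base
  shifted[lower.tri(shifted)] <- shifted[lower.tri(shifted)] + 0.1 +
    stats::rnorm(k, 0, 0.002)
  shifted[upper.tri(shifted)] <- t(shifted)[upper.tri(shifted)]
  ec_a <- structure(list(correlations = shifted, n_snps = base * 0 + 10,
                         trait_names = traits, selection_rule = "all",
                         alpha = 0.05), class = "effect_corr")
  ec_b <- structure(list(correlations = base, n_snps = base * 0 + 10,
                         trait_names = traits, selection_rule = "all",
                         alpha = 0.05), class = "effect_corr")
  cmp <- paired_t_compare(ec_a, ec_b)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$t_stat, 0)
})

test_that("the paired t matches the textbook formula on fixed differences", {
  d <- c(0.2, -0.1, 0.3, 0.0, 0.1)
  traits <- c("t1", "t2", "t3", "t4")  # 6 pairs; use 5 by masking one
  A <- diag(1, 4)
  dimnames(A) <- list(traits, traits)
  B <- A
  idx <- which(lower.tri(A))
  A[idx] <- c(d, NA)
  B[idx] <- 0
  B[idx][6] <- NA
  ec_a <- structure(list(correlations = A, n_snps = A * 0 + 5,
                         trait_names = traits, selection_rule = "all",
                         alpha = 0.05), class = "effect_corr")
  ec_b <- structure(list(correlations = B, n_snps = B * 0 + 5,
                         trait_names = traits, selection_rule = "all",
                         alpha = 0.05), class = "effect_corr")
  cmp <- paired_t_compare(ec_a, ec_b)
  t_manual <- mean(d) / (stats::sd(d) / sqrt(5))
  p_manual <- 2 * stats::pt(abs(t_manual), 4, lower.tail = FALSE)
  expect_equal(cmp$t_stat, t_manual, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_manual, tolerance = 1e-12)
  expect_equal(cmp$df, 4)
})

test_that("mismatched trait panels are rejected", {
  set.seed(5)
  ec1 <- effect_correlations(make_assoc(list(x = stats::rnorm(5),
                                             y = stats::rnorm(5))))
  ec2 <- effect_correlations(make_assoc(list(x = stats::rnorm(5),
                                             z = stats::rnorm(5))))
  expect_error(paired_t_compare(ec1, ec2), "trait panels")
})

test_that("null simulated effects are uncorrelated across independent traits", {
  cfg <- test_config(n_founders = 80, n_generations = 3, n_animals = 250,
                     n_snps = 200, n_traits = 2, seed = 303)
  sim <- simulate_dataset(cfg, pathway_h2 = 0)
  scan <- assoc_scan(sim$phenotypes, sim$genotypes, sim$A,
                     mode = "null-reuse")
  ec <- effect_correlations(scan)
  r <- ec$correlations["trait_1", "trait_2"]
  expect_lt(abs(r), 3 / sqrt(200) + 0.1)
})
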