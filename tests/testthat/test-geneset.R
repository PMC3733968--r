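test_that("proportion significant counts the threshold inclusively", {
  res <- proportion_significant(c(0.01, 0.05, 0.2, 0.8), alpha = 0.05)
  expect_equal(res$n_significant, 2)
  expect_equal(res$proportion, 0.5)
  res0 <- proportion_significant(rep(1, 10))
  expect_equal(res0$n_significant, 0)
  expect_equal(res0$proportion, 0)
  expect_error(proportion_significant(numeric()), "undefined")
  expect_error(proportion_significant(c(0.5, 1.2)), "0, 1")
})

test_that("published set-level f-values follow from the count tables", {
  ref <- rnase5_reference()
  expect_equal(ref$m, 211)
  tot <- colSums(ref$sig_counts[-1])
  expect_equal(round(tot[["protein_pct"]] / ref$m, 3), 0.270)
  expect_equal(round(tot[["protein_yield"]] / ref$m, 3), 0.227)
  expect_equal(round(tot[["fertility"]] / ref$m, 3), 0.085)
  expect_equal(round(tot[["fat_yield"]] / ref$m, 3), 0.128)
  expect_equal(round(tot[["fat_pct"]] / ref$m, 3), 0.128)
  expect_equal(round(tot[["milk_yield"]] / ref$m, 3), 0.190)
})

test_that("the m*P/S FDR reproduces published table rows with truncation", {
  expect_equal(fdr_mps(211, 0.05, 57)$percent, 18L)
  expect_equal(fdr_mps(211, 0.05, 57)$raw_percent, 100 * 211 * 0.05 / 57)
  expect_equal(fdr_mps(211, 0.05, 27)$percent, 39L)
  expect_equal(fdr_mps(211, 0.05, 48)$percent, 21L)
  expect_equal(fdr_mps(211, 0.05, 40)$percent, 26L)
  # S = m * P exactly -> 100%
  expect_equal(fdr_mps(200, 0.05, 10)$percent, 100L)
  expect_true(is.na(fdr_mps(100, 0.05, 0)$percent))
})

test_that("experiment-wise p handles boundaries and ties as documented", {
  null <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(experimentwise_p(0.25, null), 0.5)
  expect_equal(experimentwise_p(0, c(0.1, 0.2)), 1)
  expect_equal(experimentwise_p(0.9, null), 0)
  expect_equal(experimentwise_p(0.2, null), 0.75)          # tie counts
  expect_equal(experimentwise_p(0.2, null, ties = "gt"), 0.5)
  expect_error(experimentwise_p(0.5, numeric()), "empty")
})

# small universe shared by the permutation tests
toy_universe <- function() {
  genes <- tibble::tibble(gene_id = paste0("g", 1:5), chrom = "1",
                          start = c(1e6, 3e6, 5e6, 7e6, 9e6))
  genes$stop <- genes$start + 1e4
  snps <- tibble::tibble(snp_id = paste0("s", 1:25), chrom = "1",
                         pos = seq(5e5, 9.7e6, length.out = 25))
  set.seed(11)
  assoc <- tibble::tibble(snp_id = snps$snp_id,
                          p_value = stats::runif(25))
  list(genes = genes, snps = snps, assoc = assoc)
}

test_that("permutation null is reproducible and validates inputs", {
  u <- toy_universe()
  n1 <- permutation_null(u$assoc, u$genes, u$snps, n_genes = 2,
                         n_reps = 50, seed = 5)
  n2 <- permutation_null(u$assoc, u$genes, u$snps, n_genes = 2,
                         n_reps = 50, seed = 5)
  expect_identical(as.numeric(n1), as.numeric(n2))
  expect_error(permutation_null(u$assoc, u$genes, u$snps, n_genes = 2,
                                n_reps = 0), "no replicates")
  expect_error(permutation_null(u$assoc, u$genes, u$snps, n_genes = 5,
                                n_reps = 10), "larger")
  expect_true(all(n1 >= 0 & n1 <= 1))
})

test_that("the permutation null matches exhaustive subset enumeration", {
  u <- toy_universe()
  win <- build_windows(u$genes, flank = 5e5)
  sets <- utils::combn(5, 2)
  exact <- apply(sets, 2, function(k) {
    s <- assign_snps(win[k, ], u$snps)
    mean(u$assoc$p_value[u$assoc$snp_id %in% s$snp_ids] <= 0.05)
  })
  emp <- permutation_null(u$assoc, u$genes, u$snps, n_genes = 2,
                          n_reps = 10000, seed = 9)
  # total-variation distance between the empirical and exact distributions
  vals <- sort(unique(c(exact, emp)))
  tv <- 0.5 * sum(abs(
    vapply(vals, function(v) mean(abs(emp - v) < 1e-12), numeric(1)) -
      vapply(vals, function(v) mean(abs(exact - v) < 1e-12), numeric(1))))
  expect_lt(tv, 0.03)
})

test_that("replicates with empty SNP sets are redrawn and counted", {
  genes <- tibble::tibble(gene_id = c("far1", "far2", "near"),
                          chrom = c("2", "2", "1"),
                          start = c(1e6, 2e6, 1e6),
                          stop = c(1e6, 2e6, 1e6) + 1e3)
  snps <- tibble::tibble(snp_id = "s1", chrom = "1", pos = 1.2e6)
  assoc <- tibble::tibble(snp_id = "s1", p_value = 0.01)
  null <- suppressWarnings(
    permutation_null(assoc, genes, snps, n_genes = 1, n_reps = 200,
                     seed = 2))
  expect_gt(attr(null, "redraws"), 0)
  expect_true(all(null == 1))  # only the covered gene can be drawn
})

test_that("experimentwise_p is monotone non-increasing in the observed value", {
  set.seed(31)
  null <- stats::runif(500)
  obs <- seq(0, 1, by = 0.05)
  p <- vapply(obs, experimentwise_p, numeric(1), null_proportions = null)
  expect_true(all(diff(p) <= 0))
})

test_that("pathway_test assembles counts, null, P and FDR coherently", {
  u <- toy_universe()
  pt <- pathway_test(u$assoc, u$genes[1:2, ], u$genes, u$snps,
                     n_reps = 300, seed = 4)
  expect_s3_class(pt, "pathway_test")
  expect_equal(pt$proportion_significant,
               pt$n_significant / pt$n_snps_tested)
  expect_equal(pt$experimentwise_p,
               mean(pt$null_proportions >= pt$proportion_significant))
  if (pt$n_significant > 0) {
    expect_equal(pt$fdr_percent,
                 as.integer(trunc(100 * pt$n_snps_tested * 0.05 /
                                    pt$n_significant)))
  }
  g <- glance(pt)
  expect_equal(g$n_reps, 300)
  td <- tidy(pt)
  expect_equal(nrow(td), 300)
  expect_s3_class(autoplot(pt), "ggplot")
})
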