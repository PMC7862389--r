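test_that("median-of-ratios size factors normalize pure depth differences", {
  c1 <- c(10, 40, 200, 5, 17)
  counts <- cbind(s1 = c1, s2 = c1)
  rownames(counts) <- sprintf("g%d", 1:5)
  expect_equal(unname(size_factors(counts)), c(1, 1))
  # column2 = 2 x column1: factors (1/sqrt(2), sqrt(2))
  counts2 <- cbind(s1 = c1, s2 = 2 * c1)
  expect_equal(unname(size_factors(counts2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # normalized columns equal within 1e-9 for any pure depth scaling
  sf <- size_factors(cbind(a = c1, b = 7 * c1))
  norm <- sweep(cbind(a = c1, b = 7 * c1), 2, sf, "/")
  expect_lt(max(abs(norm[, 1] - norm[, 2])), 1e-9)
  # geometric mean of factors stays near 1 when all counts are positive
  # (median-of-ratios pins the median genus, so exact unity is not an
  # identity, but balanced data keep the product close to 1)
  set.seed(2)
  m <- matrix(rpois(60, 50) + 1, 10, 6)
  expect_equal(exp(mean(log(size_factors(m)))), 1, tolerance = 0.05)
  # genus with a zero never enters the reference; with no all-positive
  # genus the error advises the fallback, which then works
  sparse <- rbind(c(5, 0), c(0, 7))
  expect_error(size_factors(sparse), "pseudo_reference")
  expect_length(size_factors(sparse, pseudo_reference = TRUE), 2)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  counts <- matrix(rnbinom(200 * 8, mu = 60, size = 5), 200, 8)
  counts[sample(length(counts), 150)] <- 0
  keep <- rowSums(counts) > 0
  counts <- counts[keep, ]
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(size_factors(counts)), unname(ref),
               tolerance = 1e-10)
})

test_that("dispersion estimates are calibrated on Poisson and NB data", {
  groups <- rep(c("A", "B"), each = 25)
  set.seed(8)
  pois <- matrix(rpois(300 * 50, lambda = 100), 300, 50)
  sf <- size_factors(pois)
  disp_p <- estimate_dispersion(pois, sf, groups)
  expect_lte(stats::median(disp_p$dispersion), 0.01)
  nb <- matrix(rnbinom(300 * 100, mu = 100, size = 2), 300, 100)
  g2 <- rep(c("A", "B"), each = 50)
  disp_nb <- estimate_dispersion(nb, size_factors(nb), g2)
  covered <- mean(disp_nb$dispersion >= 0.3 & disp_nb$dispersion <= 0.7)
  expect_gte(covered, 0.9)
  # all-zero genus floored and flagged
  nb0 <- rbind(nb, 0)
  d0 <- estimate_dispersion(nb0, size_factors(nb), g2)
  expect_true(d0$all_zero[nrow(nb0)])
  expect_equal(d0$dispersion[nrow(nb0)], 1e-8)
  expect_error(estimate_dispersion(nb[, c(1, 51)], c(1, 1), c("A", "B")),
               "at least 2")
})

test_that("the Wald engine matches an independent per-genus NB MLE", {
  set.seed(13)
  n <- 16
  groups <- rep(c("A", "B"), each = n / 2)
  x <- as.numeric(groups == "B")
  sf <- exp(stats::runif(n, -0.4, 0.4))
  G <- 25
  alpha <- stats::runif(G, 0.02, 0.6)
  lfc_true <- stats::rnorm(G, 0, 1.5)
  counts <- t(vapply(seq_len(G), function(g) {
    mu <- sf * 80 * 2^(lfc_true[g] * x)
    stats::rnbinom(n, mu = mu, size = 1 / alpha[g])
  }, numeric(n)))
  rownames(counts) <- sprintf("g%02d", seq_len(G))
  res <- nb_wald_test(counts, sf, alpha, groups)
  ok <- rowSums(counts[, 1:(n / 2)]) > 0 & rowSums(counts[, -(1:(n / 2))]) > 0
  for (g in which(ok)) {
    oracle <- nb_mle_oracle(counts[g, ], sf, alpha[g], x)
    expect_equal(res$lfc[g], oracle$lfc, tolerance = 1e-4)
    expect_equal(res$se[g], oracle$se, tolerance = 1e-3)
  }
})

test_that("identical groups give zero fold change and p = 1", {
  block <- matrix(rpois(40, 30) + 1, 10, 4)
  counts <- cbind(block, block)
  rownames(counts) <- sprintf("g%d", 1:10)
  groups <- rep(c("A", "B"), each = 4)
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, groups)
  res <- nb_wald_test(counts, sf, disp$dispersion, groups)
  expect_equal(res$lfc, rep(0, 10), tolerance = 1e-6)
  expect_equal(res$pvalue, rep(1, 10), tolerance = 1e-5)
  # all-zero genera are untestable: NA p, excluded from BH's m
  counts0 <- rbind(counts, gz = 0)
  res0 <- diff_abundance(counts0, groups)
  expect_true(is.na(res0$pvalue[res0$genus == "gz"]))
  expect_true(is.na(res0$padj[res0$genus == "gz"]))
})

test_that("BH adjustment follows the step-up rule over non-NA entries", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # hand-computed step-up: p(i) * m / i with cumulative minimum from the top
  p <- c(0.005, 0.009, 0.05, 0.2, 0.9)
  expect_equal(bh_adjust(p), c(0.0225, 0.0225, 1 / 12, 0.25, 0.9))
  # NA entries do not count toward m
  with_na <- bh_adjust(c(0.01, NA, 0.02, 0.03, 0.04))
  expect_equal(with_na[!is.na(with_na)], rep(0.04, 4))
  expect_true(is.na(with_na[2]))
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")
  # monotone in the input order statistics and >= raw p
  set.seed(3)
  p2 <- runif(50)
  adj <- bh_adjust(p2)
  expect_true(all(adj >= p2))
  expect_true(all(diff(adj[order(p2)]) >= -1e-12))
})

test_that("fold-change shrinkage is the posterior mean under N(0, tau2)", {
  # lfc = 2 with se^2 = tau2 halves the estimate
  expect_equal(shrink_lfc(2, 1, tau2 = 1), 1)
  # se -> 0 leaves the MLE untouched; tau2 -> 0 kills it
  expect_equal(shrink_lfc(2, 1e-8, tau2 = 1), 2, tolerance = 1e-6)
  expect_lt(abs(shrink_lfc(2, 1, tau2 = 1e-9)), 1e-6)
  # estimated tau2: never flips a sign, never grows magnitude
  set.seed(4)
  lfc <- rnorm(200, 0, 2)
  se <- sqrt(rchisq(200, 3) / 3)
  sh <- shrink_lfc(lfc, se)
  expect_true(all(sign(sh) == sign(lfc) | sh == 0))
  expect_true(all(abs(sh) <= abs(lfc) + 1e-12))
})

test_that("concordance assigns categories by adjusted p and compares signs", {
  mk <- function(genus, lfc, padj)
    data.frame(genus = genus, baseMean = 100, lfc = lfc, lfcShrunk = lfc,
               se = 0.1, pvalue = padj, padj = padj,
               stringsAsFactors = FALSE)
  # 3 both-significant genera with signs (+,+), (+,-), (-,-) -> 2/3
  a <- mk(c("g1", "g2", "g3"), c(1, 1, -1), 0.01)
  b <- mk(c("g1", "g2", "g3"), c(2, -1, -2), 0.01)
  cc <- concordance_analysis(a, b)
  expect_equal(cc$table$concordant[cc$table$category == "both"], 2L)
  expect_equal(cc$table$percentage[cc$table$category == "both"],
               100 * 2 / 3, tolerance = 1e-12)
  # identical significant results: 100% concordant, r = 1
  a2 <- mk(sprintf("g%d", 1:10), seq(-2, 2, length.out = 10), 0.001)
  cc2 <- concordance_analysis(a2, a2)
  expect_equal(cc2$table$percentage[cc2$table$category == "both"], 100)
  expect_equal(cc2$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cc2$slope, 1, tolerance = 1e-12)
  # zero LFC counts as discordant even when significant in both
  z <- mk("g1", 0, 0.01)
  ccz <- concordance_analysis(z, z)
  expect_equal(ccz$table$concordant[ccz$table$category == "both"], 0L)
  # category totals sum to the common-genus count
  expect_equal(sum(cc$table$total), cc$n_common)
  expect_error(concordance_analysis(mk("gA", 1, 0.1), mk("gB", 1, 0.1)),
               "common")
})

test_that("genera absent from one strategy are excluded from concordance", {
  mk <- function(genus, lfc, padj)
    data.frame(genus = genus, baseMean = 10, lfc = lfc, lfcShrunk = lfc,
               se = 0.1, pvalue = padj, padj = padj,
               stringsAsFactors = FALSE)
  a <- mk(c("g1", "g2", "g3"), 1, 0.01)
  b <- mk(c("g2", "g3", "g4"), 1, 0.01)
  cc <- concordance_analysis(a, b)
  expect_equal(cc$n_common, 2)
  expect_equal(sum(cc$table$total), 2)
})
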