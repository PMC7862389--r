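test_that("pair partitions are disjoint, exhaustive, with read fractions", {
  pr <- make_pair(c(gA = 10, gB = 5, gC = 1), c(gA = 90, gB = 40, gD = 3))
  part <- partition_pair(pr)$genus
  expect_setequal(part$common, c("gA", "gB"))
  expect_equal(part$only_16s, "gC")
  expect_equal(part$only_shotgun, "gD")
  expect_length(intersect(part$common, part$only_16s), 0)
  expect_equal(part$frac_reads_common_16s, 15 / 16)
  expect_equal(part$frac_reads_common_shotgun, 130 / 133)
  # identical supports: empty exclusives, fractions 1
  pr2 <- make_pair(c(gA = 3, gB = 8), c(gA = 30, gB = 2))
  part2 <- partition_pair(pr2)$genus
  expect_length(part2$only_16s, 0)
  expect_equal(part2$frac_reads_common_16s, 1)
  expect_equal(part2$frac_reads_common_shotgun, 1)
})

test_that("dropout genera land in the shotgun-exclusive partition", {
  des <- simulation_design(seed = 77L)
  comm <- generate_true_community(des)
  p16 <- simulate_16s_profile(comm, 187500, "a_16S", seed = 1L)
  psg <- simulate_shotgun_profile(comm, 2e6, "a_sg", seed = 2L)
  pr <- make_pair(p16$counts, psg$counts)
  part <- partition_pair(pr)$genus
  dropped_seen <- intersect(names(comm$bias)[comm$bias == 0],
                            names(psg$counts))
  expect_true(all(dropped_seen %in% part$only_shotgun))
  # and exclusive genera are rarer than common ones (median shotgun count)
  expect_lt(stats::median(psg$counts[part$only_shotgun]),
            stats::median(psg$counts[part$common]))
})

test_that("pair correlation works on log2 counts of common genera", {
  # exact 16x scaling is affine on the log scale -> r = 1
  c16 <- c(gA = 2, gB = 8, gC = 64)
  pr <- make_pair(c16, 16 * c16)
  corr <- pair_correlation(pr)
  expect_equal(corr$r, 1, tolerance = 1e-12)
  expect_equal(corr$n, 3)
  # fewer than 3 common genera -> undefined flag
  expect_false(pair_correlation(make_pair(c(gA = 1, gB = 2),
                                          c(gA = 5, gB = 9)))$defined)
  # deep unbiased multinomial pair: r >= 0.95
  des <- simulation_design(dropout_fraction = 0, phantom_fraction = 0,
                           bias_log_sd = 0, seed = 19L)
  comm <- generate_true_community(des)
  pr2 <- make_pair(simulate_16s_profile(comm, 1e6, seed = 3L)$counts,
                   simulate_shotgun_profile(comm, 1e6, seed = 4L)$counts)
  expect_gte(pair_correlation(pr2)$r, 0.95)
})

test_that("detection-limit fits recover forced algebra exactly", {
  c16 <- c(gA = 2, gB = 8, gC = 64, gD = 256)
  fit <- detection_limit_fit(make_pair(c16, 16 * c16))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 4, tolerance = 1e-12)
  expect_equal(fit$threshold, 16, tolerance = 1e-12)
  expect_true(fit$intercept_ci[1] <= fit$intercept &&
                fit$intercept <= fit$intercept_ci[2])
  ident <- detection_limit_fit(make_pair(c16, c16))
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_equal(ident$threshold, 1, tolerance = 1e-12)
  # zero variance of the independent variable is refused
  expect_error(detection_limit_fit(make_pair(c(gA = 4, gB = 4, gC = 4),
                                             c(gA = 1, gB = 2, gC = 9))),
               "zero variance")
})

test_that("mean intercept tracks log2 depth ratio and grows with depth", {
  des <- simulation_design(dropout_fraction = 0, phantom_fraction = 0,
                           bias_log_sd = 0, seed = 23L)
  ratios <- c(2, 8, 32)
  n16 <- 187500
  mean_int <- vapply(ratios, function(R) {
    ints <- vapply(1:8, function(i) {
      d <- des; d$seed <- 100L * R + i
      comm <- generate_true_community(d)
      pr <- make_pair(
        simulate_16s_profile(comm, n16, seed = 11L * R + i)$counts,
        simulate_shotgun_profile(comm, R * n16, seed = 13L * R + i)$counts)
      detection_limit_fit(pr)$intercept
    }, numeric(1))
    mean(ints)
  }, numeric(1))
  expect_true(all(abs(mean_int - log2(ratios)) <= 0.5))
  expect_true(all(diff(mean_int) > 0))
})

test_that("intercept-depth correlation needs 3+ pairs and spread", {
  mk_fit <- function(intercept, depth)
    list(slope = 1, intercept = intercept, intercept_ci = c(0, 1),
         threshold = 2^intercept, n_common = 10,
         total_reads_shotgun = depth, total_reads_16s = 187500,
         pair_id = "x")
  fits <- list(mk_fit(1, 4e5), mk_fit(2, 8e5), mk_fit(3, 1.6e6),
               mk_fit(4, 3.2e6))
  res <- intercept_depth_correlation(fits)
  expect_true(res$defined)
  expect_gt(res$r, 0.9)
  expect_error(intercept_depth_correlation(fits[1:2]), "at least 3")
  same <- list(mk_fit(2, 1e6), mk_fit(2, 1e6), mk_fit(2, 1e6))
  expect_false(intercept_depth_correlation(same)$defined)
})

test_that("the undetected fraction counts genera under the threshold", {
  pr <- make_pair(c(gA = 1, gB = 1, gC = 5, gD = 9),
                  c(gA = 1, gB = 2, gC = 400, gD = 500))
  base <- detection_limit_fit(pr)
  fit16 <- base; fit16$threshold <- 16
  expect_equal(undetected_fraction(fit16, pr), 0.5)
  fit1 <- base; fit1$threshold <- 1
  expect_equal(undetected_fraction(fit1, pr), 0)
  fit_hi <- base; fit_hi$threshold <- 1e6
  expect_equal(undetected_fraction(fit_hi, pr), 1)
})

test_that("the per-pair table aggregates all pair statistics", {
  des <- simulation_design(seed = 41L)
  comm <- generate_true_community(des)
  pairs <- lapply(1:3, function(i)
    make_pair(simulate_16s_profile(comm, 187500, seed = 50L + i)$counts,
              simulate_shotgun_profile(comm, 1e6, seed = 60L + i)$counts,
              paste0("p", i)))
  tab <- pair_comparison_table(pairs)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$frac_reads_common_16s >= 0 &
                    tab$frac_reads_common_16s <= 1))
  expect_true(all(tab$threshold_reads > 0))
  expect_true(all(tab$intercept_ci_lo <= tab$intercept &
                    tab$intercept <= tab$intercept_ci_hi))
})
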