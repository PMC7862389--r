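test_that("community generation is deterministic and honours the design", {
  des <- simulation_design(n_genera = 1000, log_sd = 2.5, seed = 99L)
  c1 <- generate_true_community(des)
  c2 <- generate_true_community(des)
  expect_identical(c1, c2)
  expect_equal(sum(c1$proportions), 1, tolerance = 1e-12)
  expect_true(all(c1$bias >= 0))
  # dropout fraction materializes as b_g = 0 (phantoms excluded by design)
  expect_equal(sum(c1$bias == 0), round(0.3 * 1000))
  expect_false(any(c1$phantom & c1$bias == 0))
  # no dropout, no bias spread -> all bias factors exactly 1
  flat <- generate_true_community(
    simulation_design(dropout_fraction = 0, phantom_fraction = 0,
                      bias_log_sd = 0, seed = 1L))
  expect_true(all(flat$bias == 1))
  expect_error(generate_true_community(simulation_design(n_genera = 1)),
               "at least 2")
})

test_that("condition effects renormalize as 2^LFC mass multipliers", {
  des <- simulation_design(n_genera = 2, n_phyla = 1,
                           compartment_affected = 0.5,
                           dropout_fraction = 0, phantom_fraction = 0,
                           seed = 3L)
  base <- generate_true_community(des)
  base$proportions[] <- c(0.5, 0.5)
  # force a known effect: genus 1 up by LFC = 1 in the second level
  fx <- apply_condition_effects(base, "compartment", des)
  affected <- names(fx$true_lfc)[fx$true_lfc != 0]
  expect_length(affected, 1)  # 50% of 2 genera
  manual <- base$proportions * 2^fx$true_lfc
  manual <- manual / sum(manual)
  expect_equal(fx$levels$crop$proportions, manual, tolerance = 1e-12)
  # hand case: p = (1/2, 1/2), LFC = +1 on genus 1 -> (2/3, 1/3)
  lfc <- c(1, 0)
  mass <- c(0.5, 0.5) * 2^lfc
  expect_equal(mass / sum(mass), c(2 / 3, 1 / 3))
  # zero affected fraction leaves proportions untouched
  des0 <- simulation_design(compartment_affected = 0, seed = 5L)
  b0 <- generate_true_community(des0)
  fx0 <- apply_condition_effects(b0, "compartment", des0)
  expect_equal(fx0$levels$crop$proportions, b0$proportions)
  expect_true(all(fx0$true_lfc == 0))
})

test_that("multinomial sampling conserves depth and tracks proportions", {
  des <- simulation_design(n_genera = 400, seed = 17L)
  comm <- generate_true_community(des)
  for (depth in c(10, 1234, 200000)) {
    p <- simulate_shotgun_profile(comm, depth, "s", seed = depth)
    expect_equal(p$total_reads, depth)
  }
  # convergence to sampling proportions at high depth: within 5 binomial sd
  depth <- 1e6
  p <- simulate_shotgun_profile(comm, depth, "s", seed = 42L)
  probs <- comm$proportions
  probs[comm$phantom] <- 0
  probs <- probs / sum(probs)
  big <- names(probs)[probs > 0.005]
  obs <- stats::setNames(numeric(length(probs)), names(probs))
  obs[names(p$counts)] <- p$counts
  sd_bin <- sqrt(depth * probs[big] * (1 - probs[big]))
  expect_true(all(abs(obs[big] - depth * probs[big]) <= 5 * sd_bin))
})

test_that("16S sampling applies bias, dropout and phantom rules", {
  des <- simulation_design(n_genera = 2, n_phyla = 1, dropout_fraction = 0,
                           phantom_fraction = 0, bias_log_sd = 0, seed = 8L)
  comm <- generate_true_community(des)
  comm$proportions[] <- c(0.5, 0.5)
  comm$bias[] <- c(2, 1)
  # biased share 2/3 within 5 binomial sd at depth 1e6
  p <- simulate_16s_profile(comm, 1e6, "s", seed = 9L)
  expect_equal(unname(p$counts[1] / 1e6), 2 / 3,
               tolerance = 5 * sqrt((2 / 9) / 1e6) / (2 / 3))
  # dropout genus never observed in 16S; phantom never in shotgun
  des2 <- simulation_design(seed = 21L)
  comm2 <- generate_true_community(des2)
  dropped <- names(comm2$bias)[comm2$bias == 0]
  phantom <- names(comm2$phantom)[comm2$phantom]
  for (i in 1:3) {
    p16 <- simulate_16s_profile(comm2, 2e5, "a", seed = 100L + i)
    psg <- simulate_shotgun_profile(comm2, 2e5, "b", seed = 200L + i)
    expect_length(intersect(names(p16$counts), dropped), 0)
    expect_length(intersect(names(psg$counts), phantom), 0)
  }
  # nothing observable -> error
  comm$bias[] <- 0
  expect_error(simulate_16s_profile(comm, 10), "nothing to sample")
})

test_that("paired datasets are reproducible with complete ground truth", {
  des <- simulation_design(
    n_genera = 60, seed = 31L,
    replicates = list(caeca = c("14" = 3, "35" = 3),
                      crop = c("14" = 3, "35" = 3)))
  d1 <- generate_paired_dataset(des)
  d2 <- generate_paired_dataset(des)
  expect_identical(d1$truth, d2$truth)
  expect_identical(lapply(d1$set$profiles, `[[`, "counts"),
                   lapply(d2$set$profiles, `[[`, "counts"))
  md <- d1$set$metadata
  expect_equal(nrow(md), 24)  # 12 pairs x 2 strategies
  expect_true(all(table(md$pair_id) == 2))
  # every observed genus appears in the ground-truth bundle
  seen <- unique(unlist(lapply(d1$set$profiles, function(p)
    names(p$counts)), use.names = FALSE))
  expect_true(all(seen %in% d1$truth$genus))
  # byte-identical tables on re-write
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1); write_dataset(d2, dir2)
  for (f in c("counts_16s.tsv", "counts_shotgun.tsv", "metadata.tsv",
              "ground_truth.tsv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("the low-depth fraction is realized exactly", {
  des <- simulation_design(
    low_depth_fraction = 0.1, seed = 12L,
    replicates = list(caeca = c("14" = 10, "35" = 10),
                      crop = c("14" = 10, "35" = 10)))
  ds <- generate_paired_dataset(des)
  md <- ds$set$metadata
  depths <- vapply(ds$set$profiles[md$sample_id[md$strategy == "shotgun"]],
                   `[[`, numeric(1), "total_reads")
  expect_equal(sum(depths < 5e5), round(0.1 * 40))
})
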