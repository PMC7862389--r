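# Relative species abundance diagnostics: Preston-octave histograms,
# skewness of the log2 RSA with the paired strategy test, analytic
# rarefaction, and the read-depth quality filter with paired propagation.

#' Preston-octave histogram of a profile's abundance distribution
#'
#' Bins detected taxa by abundance octave: a taxon with count `c` lands in
#' octave `floor(log2(c))`, i.e. octave k holds taxa with counts in
#' `[2^k, 2^(k+1))`. Octaves are reported contiguously from 0 to the
#' maximum occupied octave.
#'
#' @param profile A [taxonomic_profile()].
#' @param rank `"genus"` or `"phylum"` (phylum counts are sums of member
#'   genera).
#' @return A data frame with columns `octave` and `n_taxa`.
#' @export
preston_histogram <- function(profile, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  counts <- rank_counts(profile, rank)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("profile has no detected taxa at rank ", rank)
  octave <- floor(log2(counts))
  tab <- tabulate(octave + 1L, nbins = max(octave) + 1L)
  data.frame(octave = seq_along(tab) - 1L, n_taxa = tab)
}

#' Skewness of the log2-transformed abundance distribution
#'
#' Computes the Fisher-Pearson standardized third moment
#' `g1 = m3 / m2^(3/2)` of the log2 counts over detected (nonzero) taxa.
#' Under-sampled communities truncate the rare left tail of a lognormal-type
#' RSA and push g1 upward, which is the mechanism this diagnostic tracks.
#'
#' @param profile A [taxonomic_profile()].
#' @param rank `"genus"` or `"phylum"`.
#' @return A one-row data frame: `sample_id`, `strategy`, `skewness`
#'   (`NA` when undefined), `n_taxa`, `total_reads`, `defined`. Skewness is
#'   undefined (flagged, not silently zero) with fewer than 3 detected taxa
#'   or zero variance.
#' @export
rsa_skewness <- function(profile, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  counts <- rank_counts(profile, rank)
  x <- log2(counts[counts > 0])
  n <- length(x)
  defined <- n >= 3 && stats::var(x) > 0
  skew <- NA_real_
  if (defined) {
    m2 <- mean((x - mean(x))^2)
    m3 <- mean((x - mean(x))^3)
    skew <- m3 / m2^1.5
  }
  data.frame(sample_id = profile$sample_id, strategy = profile$strategy,
             skewness = skew, n_taxa = n, total_reads = profile$total_reads,
             defined = defined, stringsAsFactors = FALSE)
}

#' Paired t-test on per-sample RSA skewness, 16S vs shotgun
#'
#' For each sample pair the genus-level (or phylum-level) skewness is
#' computed on both strategies and a classical paired Student t-test is run
#' on the differences `skew_16S - skew_shotgun` with `n - 1` degrees of
#' freedom. Pairs where either side's skewness is undefined are dropped
#' (and counted).
#'
#' @param pairs List of `sample_pair` objects (see [pair_profiles()]).
#' @param rank Taxonomic rank for the skewness.
#' @return A list: `t`, `p` (two-sided), `df`, `n_pairs`, `n_dropped`,
#'   `mean_difference`, `degenerate` (`TRUE` when the differences have zero
#'   variance; then `t` is 0 or +/-Inf and `p` 1 or 0 accordingly).
#' @export
paired_skewness_test <- function(pairs, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  s16 <- vapply(pairs, function(pr)
    rsa_skewness(pr$profile_16s, rank)$skewness, numeric(1))
  ssg <- vapply(pairs, function(pr)
    rsa_skewness(pr$profile_shotgun, rank)$skewness, numeric(1))
  ok <- !is.na(s16) & !is.na(ssg)
  d <- s16[ok] - ssg[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs with defined skewness on both sides")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = tt, p = if (mean(d) == 0) 1 else 0, df = n - 1L,
                n_pairs = n, n_dropped = sum(!ok),
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- mean(d) / (sd_d / sqrt(n))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1), df = n - 1L,
       n_pairs = n, n_dropped = sum(!ok), mean_difference = mean(d),
       degenerate = FALSE)
}

#' Analytic rarefaction curve (expected genus richness vs depth)
#'
#' Expected richness in a without-replacement subsample of `n` reads is the
#' hypergeometric formula
#' `E[S_n] = S_obs - sum_g C(N - N_g, n) / C(N, n)`, evaluated in log space
#' (via [vegan::rarefy()]) for numerical safety.
#'
#' @param profile A [taxonomic_profile()].
#' @param depths Increasing positive integer depths, each `<= total_reads`.
#' @return Data frame with columns `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(profile, depths) {
  depths <- as.numeric(depths)
  if (any(depths < 1)) stop("depths must be positive")
  if (any(depths > profile$total_reads))
    stop("depth exceeds total reads (", profile$total_reads, ") for sample ",
         profile$sample_id)
  # rarefy() warns when the rarest genus has count > 1; that is expected
  # for abundant communities and carries no information here
  rich <- vapply(depths, function(n)
    as.numeric(suppressWarnings(vegan::rarefy(profile$counts, sample = n))),
    numeric(1))
  data.frame(depth = depths, expected_richness = rich)
}

#' Read-depth quality filter with paired propagation
#'
#' Excludes shotgun profiles with strictly fewer than `min_reads` total
#' reads (samples below this depth have truncated, strongly right-skewed
#' RSAs and non-plateauing rarefaction curves) and, for balance, also
#' excludes the 16S mate of every excluded shotgun sample. The filter is
#' idempotent.
#'
#' @param set A [profile_set()].
#' @param min_reads Threshold (default 500000); exclusion is strict
#'   (`total_reads < min_reads`), a sample at exactly the threshold is kept.
#' @return A list: `included` (filtered [profile_set()]), `excluded`
#'   (data frame `sample_id`, `strategy`, `total_reads`, `reason`).
#' @export
quality_filter <- function(set, min_reads = 500000) {
  stopifnot(inherits(set, "profile_set"))
  md <- set$metadata
  total <- vapply(set$profiles[md$sample_id], `[[`, numeric(1), "total_reads")
  low_shotgun <- md$sample_id[md$strategy == "shotgun" &
                                total < min_reads]
  low_pairs <- md$pair_id[md$sample_id %in% low_shotgun]
  mates <- md$sample_id[md$pair_id %in% low_pairs &
                          md$strategy == "16S"]
  excluded_ids <- c(low_shotgun, mates)
  excl <- data.frame(
    sample_id = excluded_ids,
    strategy = md$strategy[match(excluded_ids, md$sample_id)],
    total_reads = unname(total[excluded_ids]),
    reason = c(rep(sprintf("shotgun reads < %d", min_reads),
                   length(low_shotgun)),
               rep("16S mate of excluded shotgun sample", length(mates))),
    stringsAsFactors = FALSE
  )
  keep <- setdiff(md$sample_id, excluded_ids)
  list(included = subset_samples(set, keep), excluded = excl)
}

#' Skewness table for every profile in a set
#'
#' @param set A [profile_set()].
#' @param rank Taxonomic rank.
#' @return Data frame of [rsa_skewness()] rows joined with compartment, day
#'   and pair id.
#' @export
skewness_table <- function(set, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  rows <- do.call(rbind, lapply(set$profiles, rsa_skewness, rank = rank))
  merge(rows, set$metadata[c("sample_id", "compartment", "day", "pair_id")],
        by = "sample_id", sort = FALSE)
}
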