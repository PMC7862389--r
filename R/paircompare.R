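# Per-sample-pair agreement: common/exclusive genus partition, abundance
# correlation, the detection-limit regression of log shotgun on log 16S
# abundance, and the intercept-vs-depth relationship across pairs.

#' Partition a pair's detected genera by sequencing strategy
#'
#' A genus (or phylum) counts as detected when it has at least one read.
#' Besides the three disjoint sets (common, 16S-only, shotgun-only), the
#' fraction of each strategy's reads mapping to common taxa is reported:
#' values near 1 mean the strategy-exclusive taxa are rare.
#'
#' @param pair A `sample_pair` (see [pair_profiles()]).
#' @return A list with elements `genus` and `phylum`, each containing
#'   `common`, `only_16s`, `only_shotgun` (character vectors) and
#'   `frac_reads_common_16s`, `frac_reads_common_shotgun`.
#' @export
partition_pair <- function(pair) {
  stopifnot(inherits(pair, "sample_pair"))
  out <- list()
  for (rank in c("genus", "phylum")) {
    c16 <- rank_counts(pair$profile_16s, rank)
    csg <- rank_counts(pair$profile_shotgun, rank)
    common <- intersect(names(c16), names(csg))
    out[[rank]] <- list(
      common = common,
      only_16s = setdiff(names(c16), common),
      only_shotgun = setdiff(names(csg), common),
      frac_reads_common_16s = sum(c16[common]) / sum(c16),
      frac_reads_common_shotgun = sum(csg[common]) / sum(csg)
    )
  }
  out
}

#' Pearson correlation of paired genus abundances
#'
#' Correlates the abundances of genera detected by both strategies of a
#' pair, on the log2 scale by default (all common genera have count >= 1,
#' so no pseudocount is needed).
#'
#' @param pair A `sample_pair`.
#' @param log2_scale Correlate log2 counts (default) or raw counts.
#' @return A list `r`, `p` (two-sided, from the t transform of r), `n`
#'   (common genera) and `defined`; with fewer than 3 common genera the
#'   correlation is flagged undefined rather than computed.
#' @export
pair_correlation <- function(pair, log2_scale = TRUE) {
  common <- pair$common
  if (length(common) < 3)
    return(list(r = NA_real_, p = NA_real_, n = length(common),
                defined = FALSE))
  x <- as.numeric(pair$profile_16s$counts[common])
  y <- as.numeric(pair$profile_shotgun$counts[common])
  if (log2_scale) { x <- log2(x); y <- log2(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(common),
                defined = FALSE))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common),
       defined = TRUE)
}

#' Detection-limit regression for one sample pair
#'
#' Ordinary least squares of log2 shotgun counts on log2 16S counts over
#' the pair's common genera. The intercept is the (log2) number of shotgun
#' reads expected for a genus mapped by a single 16S read, so
#' `2^intercept` acts as the shotgun-read detection limit of the 16S
#' strategy for this pair. 16S is the independent variable by construction,
#' hence plain OLS rather than a symmetric regression.
#'
#' @param pair A `sample_pair`.
#' @param conf_level Confidence level of the intercept interval
#'   (default 0.95).
#' @return A list: `slope`, `intercept`, `intercept_ci` (length 2),
#'   `threshold` (`2^intercept`, continuous, not rounded), `n_common`,
#'   `total_reads_shotgun`, `total_reads_16s`, `pair_id`.
#' @export
detection_limit_fit <- function(pair, conf_level = 0.95) {
  common <- pair$common
  if (length(common) < 3)
    stop("need at least 3 common genera for the detection-limit fit (pair ",
         pair$pair_id, ")")
  x <- log2(as.numeric(pair$profile_16s$counts[common]))
  y <- log2(as.numeric(pair$profile_shotgun$counts[common]))
  if (stats::sd(x) == 0)
    stop("zero variance of 16S abundances; regression undefined (pair ",
         pair$pair_id, ")")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # an exactly collinear pair triggers summary.lm's perfect-fit warning;
  # the zero-width interval it yields is the correct answer here
  ci <- withCallingHandlers(
    stats::confint(fit, "(Intercept)", level = conf_level),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(slope = unname(co[2]), intercept = unname(co[1]),
       intercept_ci = as.numeric(ci), threshold = 2^unname(co[1]),
       n_common = length(common),
       total_reads_shotgun = pair$profile_shotgun$total_reads,
       total_reads_16s = pair$profile_16s$total_reads,
       pair_id = pair$pair_id)
}

#' Correlation between detection-limit intercepts and shotgun depth
#'
#' Across pairs, the regression intercept tracks the log depth ratio of the
#' two strategies, so it grows with total shotgun reads when 16S depth is
#' roughly constant. Low-depth pairs are deliberately not excluded here.
#'
#' @param fits List of [detection_limit_fit()] results (>= 3).
#' @return A list `r`, `p`, `n`, `defined` (`FALSE` when either variable
#'   has zero variance).
#' @export
intercept_depth_correlation <- function(fits) {
  if (length(fits) < 3) stop("need at least 3 detection fits")
  ic <- vapply(fits, `[[`, numeric(1), "intercept")
  depth <- vapply(fits, `[[`, numeric(1), "total_reads_shotgun")
  if (stats::sd(ic) == 0 || stats::sd(depth) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(fits),
                defined = FALSE))
  ct <- stats::cor.test(ic, depth)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(fits),
       defined = TRUE)
}

#' Fraction of shotgun-detected genera below the detection limit
#'
#' Counts the genera whose shotgun read count is positive but strictly
#' below the pair's detection threshold `2^intercept`: these are the genera
#' most likely missed by 16S sequencing at this pair's depths.
#'
#' @param fit A [detection_limit_fit()] result.
#' @param pair The corresponding `sample_pair`.
#' @return Fraction in `[0, 1]`.
#' @export
undetected_fraction <- function(fit, pair) {
  counts <- pair$profile_shotgun$counts
  detected <- counts > 0
  sum(detected & counts < fit$threshold) / sum(detected)
}

#' Per-pair agreement table
#'
#' Runs [partition_pair()], [pair_correlation()], [detection_limit_fit()]
#' and [undetected_fraction()] for every pair and assembles the flat table
#' the pair-comparison stage reports.
#'
#' @param pairs List of `sample_pair` objects.
#' @param conf_level Confidence level for intercept intervals.
#' @return Data frame, one row per pair, with partition sizes, read
#'   fractions, correlation, regression parameters, threshold and the
#'   fraction of genera below it. Pairs where the fit is impossible carry
#'   `NA`s.
#' @export
pair_comparison_table <- function(pairs, conf_level = 0.95) {
  rows <- lapply(pairs, function(pr) {
    part <- partition_pair(pr)$genus
    corr <- pair_correlation(pr)
    fit <- tryCatch(detection_limit_fit(pr, conf_level),
                    error = function(e) NULL)
    data.frame(
      pair_id = pr$pair_id, compartment = pr$compartment, day = pr$day,
      n_common = length(part$common),
      n_16s_only = length(part$only_16s),
      n_shotgun_only = length(part$only_shotgun),
      frac_reads_common_16s = part$frac_reads_common_16s,
      frac_reads_common_shotgun = part$frac_reads_common_shotgun,
      total_reads_16s = pr$profile_16s$total_reads,
      total_reads_shotgun = pr$profile_shotgun$total_reads,
      r = corr$r, r_pvalue = corr$p,
      slope = if (is.null(fit)) NA_real_ else fit$slope,
      intercept = if (is.null(fit)) NA_real_ else fit$intercept,
      intercept_ci_lo = if (is.null(fit)) NA_real_ else fit$intercept_ci[1],
      intercept_ci_hi = if (is.null(fit)) NA_real_ else fit$intercept_ci[2],
      threshold_reads = if (is.null(fit)) NA_real_ else fit$threshold,
      frac_genera_below_threshold =
        if (is.null(fit)) NA_real_ else undetected_fraction(fit, pr),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
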