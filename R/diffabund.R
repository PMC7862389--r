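# Self-contained negative-binomial differential-abundance engine:
# median-of-ratios normalization, moment-based dispersion estimation with
# trend shrinkage, a vectorized NB GLM Wald test, BH adjustment,
# empirical-Bayes fold-change shrinkage, and the cross-strategy
# concordance analysis. The engine is a documented simplification of the
# standard RNA-seq-style NB workflow: no outlier refitting, no independent
# filtering, and a two-parameter a0 + a1/mu dispersion trend.

#' Median-of-ratios size factors
#'
#' The reference pseudo-sample is the per-genus geometric mean across
#' samples, computed over genera with all-positive counts; each sample's
#' size factor is the median over those genera of count/reference. With
#' `pseudo_reference = TRUE` the geometric mean is instead taken over the
#' positive counts of each genus (positive-counts fallback for sparse
#' matrices where no genus is positive everywhere).
#'
#' @param counts Genus x sample matrix of non-negative integers.
#' @param pseudo_reference Use the positive-counts geometric mean fallback.
#' @return Named positive numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  logc <- log(counts)
  if (pseudo_reference) {
    pos <- counts > 0
    logmeans <- rowSums(ifelse(pos, logc, 0)) / ncol(counts)
    logmeans[rowSums(pos) == 0] <- -Inf
  } else {
    logmeans <- rowMeans(logc)
  }
  use <- is.finite(logmeans)
  if (!any(use)) {
    if (!pseudo_reference)
      stop("no genus has positive counts in every sample; ",
           "retry with pseudo_reference = TRUE")
    stop("count matrix has no positive entries")
  }
  sf <- apply(counts, 2, function(col) {
    ratios <- log(col[use]) - logmeans[use]
    exp(stats::median(ratios[is.finite(ratios)]))
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor; counts too sparse for this reference")
  sf
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' Per genus, the raw negative-binomial dispersion is estimated from
#' normalized counts as `alpha = max((s2 - mu) / mu^2, 1e-8)` where `s2` is
#' the pooled within-group variance and `mu` the overall mean. Raw
#' estimates are then shrunk toward a fitted mean-dispersion trend
#' `a0 + a1/mu` by equally weighted geometric averaging, stabilizing
#' genus-level estimates at small sample sizes.
#'
#' @param counts Genus x sample count matrix.
#' @param sf Size factors from [size_factors()].
#' @param groups Factor/vector of two condition labels, one per sample,
#'   each level with at least 2 samples.
#' @return Data frame with `mean` (normalized), `dispersion_raw`,
#'   `dispersion_trend`, `dispersion` (final) and `all_zero` flag, one row
#'   per genus.
#' @export
estimate_dispersion <- function(counts, sf, groups) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2))
    stop("each condition needs at least 2 samples")
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  lev <- levels(groups)
  n1 <- sum(groups == lev[1]); n2 <- sum(groups == lev[2])
  v1 <- apply(norm[, groups == lev[1], drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, groups == lev[2], drop = FALSE], 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  floor_disp <- 1e-8
  raw <- pmax((s2 - mu) / mu^2, floor_disp)
  all_zero <- mu == 0
  raw[all_zero] <- floor_disp
  # trend a0 + a1/mu fitted by least squares on informative genera
  use <- !all_zero & raw > floor_disp & is.finite(raw)
  if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
    a <- pmax(stats::coef(fit), 0)
    trend <- pmax(a[1] + a[2] / mu, floor_disp)
  } else {
    trend <- rep(max(stats::median(raw[!all_zero]), floor_disp),
                 length(raw))
  }
  trend[all_zero] <- floor_disp
  final <- exp(0.5 * log(raw) + 0.5 * log(trend))
  data.frame(mean = mu, dispersion_raw = raw, dispersion_trend = trend,
             dispersion = final, all_zero = all_zero,
             row.names = rownames(counts))
}

# Vectorized IRLS fit of per-genus NB GLMs with log link and design
# intercept + group, dispersions fixed. Returns natural-log coefficients,
# standard errors from the observed Fisher information, and convergence
# flags. The group coefficient is bounded at +/- 10 log2 units so fits with
# a structural zero in one group stay finite.
nb_glm_two_group <- function(counts, sf, dispersion, groups,
                             max_iter = 100, tol = 1e-10) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  lev <- levels(groups)
  x <- as.numeric(groups == lev[2])
  G <- nrow(counts); n <- ncol(counts)
  sfm <- matrix(sf, G, n, byrow = TRUE)
  xm <- matrix(x, G, n, byrow = TRUE)
  alpha <- dispersion
  norm <- counts / sfm
  m0 <- rowSums(norm * (1 - xm)) / sum(1 - x)
  m1 <- rowSums(norm * xm) / sum(x)
  cap <- 10 * log(2)
  b0 <- log(pmax(m0, 1e-8))
  b1 <- pmin(pmax(log(pmax(m1, 1e-8)) - b0, -cap), cap)
  converged <- rep(FALSE, G)
  active <- rep(TRUE, G)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    eta <- matrix(b0, G, n) + outer(b1, x)
    mu <- sfm * exp(eta)
    denom <- 1 + alpha * mu
    r <- (counts - mu) / denom        # score weight per cell
    w <- mu / denom                   # expected information weight
    A <- rowSums(w)
    B <- rowSums(w * xm)
    u0 <- rowSums(r)
    u1 <- rowSums(r * xm)
    det <- B * (A - B)
    ok <- active & det > 1e-12
    d0 <- ifelse(ok, (u0 - u1) / (A - B), 0)
    d1 <- ifelse(ok, (-B * u0 + A * u1) / det, 0)
    # fall back to intercept-only update when the group-1 information
    # vanishes (all counts structurally zero at the cap)
    d0[active & !ok] <- (u0 / A)[active & !ok]
    # damp Newton steps so overdispersed genera cannot overshoot into
    # overflow; within +/-5 on the log scale the iteration is stable
    d0 <- pmin(pmax(d0, -5), 5)
    d1 <- pmin(pmax(d1, -5), 5)
    d0[!is.finite(d0)] <- 0
    d1[!is.finite(d1)] <- 0
    b0 <- pmin(pmax(b0 + ifelse(active, d0, 0), log(1e-12)), 50)
    b1new <- pmin(pmax(b1 + ifelse(active, d1, 0), -cap), cap)
    step <- pmax(abs(d0), abs(b1new - b1))
    b1 <- b1new
    newly <- active & step < tol
    converged[newly] <- TRUE
    active <- active & !newly
  }
  eta <- matrix(b0, G, n) + outer(b1, x)
  mu <- sfm * exp(eta)
  denom <- 1 + alpha * mu
  w_obs <- mu * (1 + alpha * counts) / denom^2
  A <- rowSums(w_obs)
  B <- rowSums(w_obs * xm)
  var_b1 <- ifelse(B * (A - B) > 0, A / (B * (A - B)), Inf)
  list(b0 = b0, b1 = b1, se_b1 = sqrt(var_b1), converged = converged,
       baseMean = rowMeans(counts / sfm))
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits, per genus, an NB generalized linear model with log link, design
#' `~ group`, and known dispersion; the log2 fold change is the group
#' coefficient, its standard error comes from the observed Fisher
#' information, and the two-sided p-value from the normal reference of the
#' Wald statistic. Genera with all-zero counts get `NA` p-values and do not
#' count toward the multiple-testing burden.
#'
#' @param counts Genus x sample count matrix.
#' @param sf Size factors.
#' @param dispersions Per-genus dispersion vector (see
#'   [estimate_dispersion()]).
#' @param groups Two-level factor; the fold change is level 2 vs level 1.
#' @return Data frame: `genus`, `baseMean`, `lfc` (log2), `se`, `stat`,
#'   `pvalue`, `converged`.
#' @export
nb_wald_test <- function(counts, sf, dispersions, groups) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2))
    stop("each group needs at least 2 samples")
  fit <- nb_glm_two_group(counts, sf, dispersions, groups)
  lfc <- fit$b1 / log(2)
  se <- fit$se_b1 / log(2)
  stat <- ifelse(is.finite(se) & se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  all_zero <- rowSums(counts) == 0
  p[all_zero] <- NA_real_
  lfc[all_zero] <- NA_real_
  data.frame(genus = rownames(counts), baseMean = fit$baseMean,
             lfc = lfc, se = se, stat = stat, pvalue = p,
             converged = fit$converged & !all_zero,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over the non-`NA` entries (so untestable genera
#' do not inflate the multiple-testing burden); `NA`s propagate.
#'
#' @param pvalues Numeric vector in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  bad <- !is.na(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad)) stop("p-values outside [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' A zero-centred normal prior `N(0, tau^2)` is combined with the per-genus
#' normal likelihood `N(lfc, se^2)`; the shrunken estimate is the posterior
#' mean `lfc * tau^2 / (tau^2 + se^2)`. The prior variance is estimated by
#' moment matching, `tau^2 = max(var(lfc) - mean(se^2), 1e-6)`, so noisy
#' estimates (large `se`) are pulled strongly toward zero while precise
#' ones move little. Shrinkage never flips a sign.
#'
#' @param lfc Vector of MLE log2 fold changes (`NA` allowed).
#' @param se Corresponding standard errors.
#' @param tau2 Optional prior variance override; estimated when `NULL`.
#' @return Vector of shrunken log2 fold changes.
#' @export
shrink_lfc <- function(lfc, se, tau2 = NULL) {
  ok <- !is.na(lfc) & is.finite(se)
  if (is.null(tau2)) {
    tau2 <- max(stats::var(lfc[ok]) - mean(se[ok]^2), 1e-6)
    if (!is.finite(tau2)) tau2 <- 1e-6
  }
  out <- lfc
  out[ok] <- lfc[ok] * tau2 / (tau2 + se[ok]^2)
  out
}

#' Run the full differential-abundance workflow for one strategy
#'
#' Normalization (with automatic positive-counts fallback when no genus is
#' positive in every sample), dispersion estimation, the NB Wald test, BH
#' adjustment and fold-change shrinkage, in order.
#'
#' @param counts Genus x sample count matrix.
#' @param groups Two-level factor over samples (level 2 vs level 1).
#' @return Data frame: `genus`, `baseMean`, `lfc`, `lfcShrunk`, `se`,
#'   `pvalue`, `padj`, `converged`.
#' @export
diff_abundance <- function(counts, groups) {
  counts <- as.matrix(counts)
  sf <- tryCatch(size_factors(counts),
                 error = function(e) size_factors(counts,
                                                  pseudo_reference = TRUE))
  disp <- estimate_dispersion(counts, sf, groups)
  res <- nb_wald_test(counts, sf, disp$dispersion, groups)
  res$padj <- bh_adjust(res$pvalue)
  res$lfcShrunk <- shrink_lfc(res$lfc, res$se)
  res[c("genus", "baseMean", "lfc", "lfcShrunk", "se", "pvalue", "padj",
        "converged")]
}

#' Differential abundance for one strategy of a profile set
#'
#' @param set A [profile_set()] (typically quality-filtered).
#' @param strategy `"16S"` or `"shotgun"`.
#' @param contrast `"compartment"` (crop vs caeca, all retained samples) or
#'   `"day"` (day 35 vs day 14; day-1 samples are excluded from this
#'   contrast).
#' @param compartment_subset For the day contrast, optionally restrict to
#'   one compartment (`"caeca"` or `"crop"`); `NULL` pools both.
#' @return As [diff_abundance()].
#' @export
diff_abundance_set <- function(set, strategy = c("16S", "shotgun"),
                               contrast = c("compartment", "day"),
                               compartment_subset = NULL) {
  strategy <- match.arg(strategy)
  contrast <- match.arg(contrast)
  md <- set$metadata[set$metadata$strategy == strategy, ]
  if (contrast == "compartment") {
    groups <- factor(md$compartment, levels = c("caeca", "crop"))
    samples <- md$sample_id
  } else {
    keep <- md$day %in% c(14L, 35L)
    if (!is.null(compartment_subset))
      keep <- keep & md$compartment == compartment_subset
    samples <- md$sample_id[keep]
    groups <- factor(md$day[keep], levels = c(14L, 35L))
  }
  counts <- profile_matrix(set, strategy, samples)
  diff_abundance(counts, groups)
}

#' Cross-strategy concordance of differential-abundance calls
#'
#' Restricts both result tables to their common genera, assigns each genus
#' to one of four significance categories (adjusted p below `alpha` in
#' both strategies / 16S only / shotgun only / neither) and counts, per
#' category, the genera whose fold changes agree in sign between the two
#' strategies. A zero (or `NA`) fold change on either side counts as
#' discordant. Pearson's r and the least-squares line of shotgun-vs-16S
#' fold changes are computed over the both-significant category only.
#'
#' @param res_16s,res_shotgun Results from [diff_abundance()] for the same
#'   contrast under each strategy.
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.05); `NA` adjusted p counts as not significant.
#' @param use_shrunken Compare signs (and correlate) shrunken fold changes
#'   (default) or raw MLE fold changes.
#' @return A list: `table` (data frame with `category`, `concordant`,
#'   `total`, `percentage`), `n_common`, `pearson_r`, `pearson_p`, `slope`,
#'   `intercept`.
#' @export
concordance_analysis <- function(res_16s, res_shotgun, alpha = 0.05,
                                 use_shrunken = TRUE) {
  common <- intersect(res_16s$genus, res_shotgun$genus)
  if (!length(common)) stop("no common genera between the two result sets")
  a <- res_16s[match(common, res_16s$genus), ]
  b <- res_shotgun[match(common, res_shotgun$genus), ]
  col <- if (use_shrunken) "lfcShrunk" else "lfc"
  sig_a <- !is.na(a$padj) & a$padj < alpha
  sig_b <- !is.na(b$padj) & b$padj < alpha
  category <- ifelse(sig_a & sig_b, "both",
                     ifelse(sig_a, "16S-only",
                            ifelse(sig_b, "shotgun-only", "neither")))
  sa <- sign(a[[col]]); sb <- sign(b[[col]])
  concordant <- !is.na(sa) & !is.na(sb) & sa != 0 & sb != 0 & sa == sb
  cats <- c("both", "16S-only", "shotgun-only", "neither")
  tab <- data.frame(
    category = cats,
    concordant = vapply(cats, function(k) sum(concordant[category == k]),
                        integer(1)),
    total = vapply(cats, function(k) sum(category == k), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$percentage <- ifelse(tab$total > 0,
                           100 * tab$concordant / tab$total, NA_real_)
  both <- category == "both"
  r <- p_r <- slope <- intercept <- NA_real_
  if (sum(both) >= 3 &&
      stats::sd(a[[col]][both]) > 0 && stats::sd(b[[col]][both]) > 0) {
    ct <- stats::cor.test(a[[col]][both], b[[col]][both])
    r <- unname(ct$estimate); p_r <- ct$p.value
    fit <- stats::lm(b[[col]][both] ~ a[[col]][both])
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  list(table = tab, n_common = length(common), pearson_r = r,
       pearson_p = p_r, slope = slope, intercept = intercept)
}
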