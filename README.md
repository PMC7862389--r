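# metacompare

Tools for asking a practical question in microbiome studies: **when the same
biological samples are profiled by both 16S rRNA amplicon sequencing and
whole-metagenome shotgun sequencing, how much do the two genus-level
taxonomic profiles agree, and where do they diverge?** The package targets
paired designs — each biological sample sequenced under both strategies —
with experimental factors such as gut compartment and sampling time, as in
poultry or other animal gut studies.

## What it computes

Starting from two genus × sample count tables (one per strategy, with a
phylum lineage column) and a metadata table that pairs them, the package
runs four linked analyses:

1. **RSA diagnostics and depth filtering.** Per-sample relative species
   abundance (RSA) histograms in Preston octaves (octave *k* holds genera
   with counts in [2ᵏ, 2ᵏ⁺¹)), the Fisher–Pearson skewness
   g₁ = m₃/m₂^(3/2) of the log₂-transformed nonzero counts, a paired
   Student t-test of skewness between strategies, analytic
   (hypergeometric) rarefaction curves
   E[Sₙ] = S_obs − Σ_g C(N−N_g, n)/C(N, n), and a quality filter that
   drops shotgun samples under a read threshold (default 500,000)
   together with their 16S mates. Under-sampling truncates the rare left
   tail of the RSA and inflates its skewness, so skewness-versus-depth is
   the core depth diagnostic.
2. **Differential abundance and concordance.** A self-contained
   negative-binomial engine: median-of-ratios size factors, moment-based
   dispersion estimates shrunk toward an a₀ + a₁/μ trend, per-genus NB GLM
   Wald tests (log link, two-group design), Benjamini–Hochberg adjustment,
   and empirical-Bayes fold-change shrinkage toward zero
   (posterior mean = LFC·τ²/(τ²+SE²)). The concordance analysis then
   classifies the genera common to both strategies into four significance
   categories (both / 16S-only / shotgun-only / neither, adjusted p < 0.05)
   and reports the share of sign-concordant fold changes per category.
3. **Per-pair detection limits.** For each sample pair, OLS of log₂
   shotgun counts on log₂ 16S counts over common genera; the intercept is
   the log₂ shotgun read count corresponding to a single 16S read, so
   2^intercept acts as the 16S detection limit expressed in shotgun reads.
   Across pairs the intercept tracks total shotgun depth.
4. **Ordination of strategy-exclusive genus subsets.** Bray–Curtis
   distances on size-factor-normalized counts, classical PCoA, and mean
   silhouette scores of condition labellings for four genus subsets: all
   genera detected by shotgun (SHOTGUN), all by 16S (16S), and the
   dataset-level exclusive sets (SHOTGUNex, 16Sex). This quantifies
   whether the genera only one strategy sees still carry the experimental
   signal.

A paired-profile **simulator** generates realistic synthetic datasets with
known ground truth — lognormal communities, per-genus 16S amplification
bias, primer dropout (shotgun-exclusive genera), database "phantom"
genera (16S-exclusive), condition-dependent fold changes, and per-sample
depths spanning the low-depth regime — so every stage can be validated
end to end.

## Worked example

```r
library(metacompare)

cfg <- run_config(design = simulation_design(seed = 1L), seed = 1L)
out <- run_all(cfg)
```

prints the stage log:

```
[metacompare] simulating paired dataset (seed 1)
[metacompare] 156 profiles, 78 pairs, 0 unpaired
[metacompare] paired skewness t = 7.996, p = 1.04e-11
[metacompare] quality filter: 34 samples excluded, 61 pairs kept
[metacompare] compartment 16S: 163/280 genera significant (padj < 0.05)
[metacompare] compartment shotgun: 214/380 genera significant (padj < 0.05)
[metacompare] day 16S: 35/279 genera significant (padj < 0.05)
[metacompare] day shotgun: 59/380 genera significant (padj < 0.05)
[metacompare] detection: mean r = 0.959, intercept-depth r = 0.928
```

Reading the log: 16S skewness exceeds shotgun skewness strongly
(t = 8.0, paired over 78 pairs) because the shallower, biased 16S samples
truncate the rare tail of the RSA; 17 shotgun samples fall below 500,000
reads and are removed with their mates (34 profiles), leaving 61 pairs;
shotgun calls more significant genera than 16S for both contrasts
(214 vs 163 and 59 vs 35) because it reaches further down the abundance
scale; per-pair abundance correlations average r ≈ 0.96 over common
genera; and the detection-limit intercepts correlate with total shotgun
reads at r = 0.93. The returned object carries the full tables
(`out$report$concordance`, `out$report$detection$per_pair`,
`out$report$stratification`, …).

Individual stages are plain functions on small objects, e.g.:

```r
des  <- simulation_design(seed = 1L)
comm <- generate_true_community(des)
p    <- simulate_shotgun_profile(comm, depth = 2e6, seed = 7L)
preston_histogram(p)        # octave histogram
rsa_skewness(p)$skewness    # g1 of the log2 RSA
rarefaction_curve(p, c(1e4, 1e5, 1e6))
```

A thin command-line front end is installed under
`system.file("scripts", "metacompare", package = "metacompare")` with
`simulate` and `run` subcommands.

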