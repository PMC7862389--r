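---
title: "Comparing paired 16S and shotgun taxonomic profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing paired 16S and shotgun taxonomic profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacompare)
```

## The problem

16S rRNA amplicon sequencing and whole-metagenome shotgun sequencing are
both used to profile microbial communities, but they do not see the same
thing. Amplicon sequencing is cheap and works at modest depth, yet primer
choice biases which taxa amplify, some taxa drop out entirely, and the
reference databases used for amplicon and shotgun classification do not
agree genus-for-genus. Shotgun sequencing is unbiased at the
fragmentation step and reaches further down the abundance scale — but
only when enough reads are available. When the same DNA extracts are
sequenced both ways, the paired design lets each strategy act as the
other's control. This package implements the comparison framework:
depth diagnostics on the relative species abundance distribution (RSA),
cross-strategy concordance of differential-abundance calls, per-pair
detection-limit regression, and ordination of the genus subsets each
strategy sees exclusively.

All analyses start from genus-level integer count tables. Read
processing, taxonomic assignment and any harmonization of genus names
between the two strategies' databases are assumed done upstream; genus
identity is by exact name string.

## Depth diagnostics on the RSA

For one sample, the RSA counts how many genera occur at each abundance.
We bin it in Preston octaves — octave $k$ holds genera with counts in
$[2^k, 2^{k+1})$, i.e. octave $\lfloor \log_2 c \rfloor$ for count $c$ —
using the simple floor rule throughout (no half-splitting of boundary
counts; the simple rule is exactly reproducible and the paired test
below only uses differences, which are insensitive to the convention).

The shape statistic is the Fisher–Pearson standardized third moment of
the $\log_2$ counts over *detected* genera (no pseudocount — the RSA is
defined over what was seen):

$$g_1 = \frac{m_3}{m_2^{3/2}}, \qquad
  m_j = \tfrac{1}{S}\sum_{g}\bigl(\log_2 c_g - \overline{\log_2 c}\bigr)^j.$$

We use the population estimator without small-sample bias correction;
the downstream paired t-test operates on within-pair differences and is
unaffected by a common scale factor. Skewness is reported as undefined
(flagged, never silently zero) below 3 detected genera or at zero
variance.

Why skewness: a community whose true abundances are lognormal has a
symmetric RSA on the log scale. Finite sampling truncates the rare left
tail — genera expected at less than ~1 read go unseen — so an
under-sampled profile is *right-skewed*. Mean skewness therefore
decreases monotonically with read depth, which the test suite verifies
on simulated communities across depths $2\cdot10^4$, $2\cdot10^5$,
$2\cdot10^6$ (50 replicate communities, fixed seeds). The paired
Student t-test on per-pair skewness differences (df $= n-1$) quantifies
the systematic 16S-vs-shotgun shape difference.

Rarefaction curves use the analytic hypergeometric expectation
$E[S_n] = S_{obs} - \sum_g \binom{N-N_g}{n}\big/\binom{N}{n}$,
evaluated in log space via `vegan::rarefy` and validated against
Monte-Carlo subsampling in the tests.

**Quality filter.** Shotgun samples with fewer than 500,000 reads
(strict inequality; the threshold is configurable) are excluded, and —
for a balanced paired comparison — so are their 16S mates. The filter is
idempotent and reports every exclusion with its reason.

## The differential-abundance engine

The engine is a deliberately self-contained implementation of the
standard negative-binomial count workflow, so that every step is
testable in isolation. It simplifies the full RNA-seq-style machinery in
three documented ways: no outlier detection/refitting, no independent
filtering of low-count genera, and a two-parameter dispersion trend.

* **Normalization.** Median-of-ratios size factors: reference
  $= $ per-genus geometric mean over samples (genera with all-positive
  counts only); size factor $=$ median of count/reference. The
  implementation is numerically identical to the reference
  implementation in DESeq2 (cross-checked to $10^{-10}$ in the tests).
  When no genus is positive everywhere, a positive-counts fallback
  computes the geometric mean over positive entries only; the pipeline
  applies it automatically on sparse strategy matrices.
* **Dispersion.** Per genus, method of moments on normalized counts,
  $\hat\alpha_g = \max\{(s^2_g - \bar\mu_g)/\bar\mu_g^2,\ 10^{-8}\}$,
  with $s^2_g$ the pooled within-condition variance. A mean–dispersion
  trend $a_0 + a_1/\mu$ is fitted by least squares over informative
  genera and each estimate is shrunk toward the trend by equally
  weighted geometric averaging. Simulations in the test suite confirm
  calibration: Poisson data yield median $\hat\alpha \le 0.01$ and NB
  data with $\alpha = 0.5$ land in $[0.3, 0.7]$ for $\ge 90\%$ of genera
  at $n = 100$.
* **Testing.** Per genus, an NB GLM with log link and design
  intercept + group, dispersion held fixed, is fitted by iteratively
  reweighted least squares vectorized across genera (closed-form
  $2\times2$ solves). Standard errors come from the observed Fisher
  information; the Wald statistic LFC/SE is referred to the standard
  normal, two-sided. Fold-change estimates are bounded at $\pm 10$
  log$_2$ units and Newton steps damped to $\pm5$ per iteration so
  genera absent from one condition retain finite, testable estimates;
  non-convergence after 100 iterations is flagged. An independent
  `optim()`-based per-genus maximum-likelihood oracle in the tests
  agrees with the vectorized fits to $10^{-4}$.
* **Multiple testing.** Benjamini–Hochberg step-up over non-`NA`
  p-values (all-zero genera are untestable and excluded from the
  burden), via `stats::p.adjust`.
* **Shrinkage.** Empirical-Bayes normal prior $N(0, \tau^2)$ with
  $\tau^2 = \max\{\mathrm{var}(\widehat{LFC}) - \overline{SE^2},\
  10^{-6}\}$ by moment matching; the shrunken value is the posterior
  mean $\widehat{LFC}\,\tau^2/(\tau^2 + SE^2)$. Shrinkage never flips a
  sign and never increases magnitude.

Type-I calibration of the whole chain is verified on null NB
simulations (2,000 genera, 10 + 10 samples): the raw-p rejection rate at
0.05 lies in $[0.03, 0.07]$ and the BH discovery rate stays within
Monte-Carlo noise of the nominal level.

**Concordance.** Over the genera common to both strategies' result
tables, each genus falls in one of four categories by adjusted
$p < 0.05$ (both / 16S-only / shotgun-only / neither); within each
category we report the share whose fold changes agree in sign.
Sign comparison uses the shrunken LFC by default (a flag switches to
raw MLE signs); a zero or missing LFC counts as discordant. Pearson's r
and the least-squares line are computed on the both-significant category
only.

## Detection-limit regression

For each pair, ordinary least squares of $\log_2$ shotgun counts on
$\log_2$ 16S counts over common genera (all counts $\ge 1$, so no
pseudocount). OLS rather than a symmetric regression because the roles
are asymmetric by design: 16S abundance is the predictor. The intercept
estimates the $\log_2$ shotgun read count of a genus seen by exactly one
16S read, so $2^{\text{intercept}}$ is a per-pair detection limit in
shotgun-read units, reported as a continuous value. The 95% confidence
interval uses the t quantile times the intercept's standard error
(level configurable). With unbiased multinomial sampling at a
shotgun:16S depth ratio $R$, the intercept recovers $\log_2 R$ — the
suite checks ratio 16 (3,000,000 vs 187,500 reads, the nominal amplicon
depth) to within $\pm 0.5$ with slope in $[0.9, 1.1]$ over 20 seeds —
and across pairs the intercept rises with total shotgun depth. The
fraction of shotgun-detected genera with counts below the threshold
estimates how much of the community the 16S assay misses in that pair;
low-depth pairs are deliberately retained in the intercept–depth
correlation.

## Ordination and silhouette stratification

Counts are normalized per strategy by the size factors above (computed
once on the full strategy matrix, so restricting the genus subset never
changes the normalization), then Bray–Curtis dissimilarity
$\mathrm{BC}(i,j) = \sum_g |x_{ig}-x_{jg}| \,/\, \sum_g (x_{ig}+x_{jg})$
is computed over the dataset-wide genus axis (zeros for undetected
genera, so all samples share one coordinate system). Classical PCoA
(Gower double-centering of $-D^2/2$, symmetric eigendecomposition,
coordinates $=$ eigenvector $\times \sqrt{\lambda}$) is provided for
visualization; negative-eigenvalue axes — possible for Bray–Curtis —
are dropped with their total inertia reported, and no Cailliez/Lingoes
correction is applied by default.

Cluster quality uses the mean silhouette
$s_i = (b_i - a_i)/\max(a_i, b_i)$ with $a_i$ the mean intra-group
distance and $b_i$ the smallest mean distance to another group;
singleton-group samples score 0. The silhouette is evaluated on the
Bray–Curtis distances restricted to the genus subset rather than on a
truncated PCoA embedding: keeping all positive axes makes the two
equivalent, and a fixed axis cut would introduce an arbitrary parameter.

Four genus subsets are scored: SHOTGUN and 16S (all genera each strategy
detects anywhere in the dataset) and SHOTGUNex / 16Sex (detected by one
strategy in at least one sample and by the other in none — exclusivity
is a dataset-level property, not per-pair). Each subset is scored for
compartment labels over all samples and for day labels within each
compartment.

## The simulator

`simulation_design()` fixes the study conditions; its defaults emulate
the paired chicken-gut benchmark the framework was built around:

| parameter | default | meaning |
|---|---|---|
| `n_genera`, `n_phyla` | 400, 14 | community size; a few hundred genera is the observed order of magnitude |
| `log_sd` | 2.5 | lognormal RSA spread (natural log), giving realistic rare tails |
| `replicates` | caeca 4/16/20, crop 5/15/18 | pairs per (compartment, day 1/14/35) cell; 78 pairs total |
| `depth_16s` | U[150,000; 200,000] | around the nominal MiSeq output of ~187,500 reads/sample |
| `depth_shotgun` | LogU[200,000; 5,000,000] | spans the low-depth regime; ~28% of samples fall under 500,000 reads, matching the observed 28/78 |
| `dropout_fraction` | 0.3 | genera with 16S bias exactly 0 (shotgun-exclusive) |
| `phantom_fraction` | 0.05 | 16S-exclusive genera (database disagreement stand-in) |
| `bias_log_sd` | 0.5 | lognormal spread of the 16S bias factor $b_g$ around 1 |
| `compartment_affected`, `compartment_lfc_sd` | 0.5, 2 | fraction of genera changed between compartments; log2 effect spread |
| `day_affected`, `day_lfc_sd` | 0.2, 1 | likewise for sampling time (weaker, as observed) |

Reads are multinomial draws: shotgun samples from the community
proportions directly (no genome-size weighting — read counts are taken
as abundance proxies, and all strategy distortions are folded into
$b_g$); 16S samples with probabilities $\propto p_g b_g$, plus the
phantom genera at their own small proportions. Phantom genera are drawn
from the low-abundance half of the community and receive no condition
effects — they emulate classification artifacts, not biology — which is
why their silhouette against sampling time sits near zero. This phantom
model is a stand-in: no quantitative mechanism for 16S-exclusive genera
is established, so the simulator implements the simplest model that
reproduces their observed phenomenology (present, rare, uninformative).
Dropout genera, in contrast, are real community members invisible to
16S, and they do inherit condition effects — which is what lets the
SHOTGUNex subset retain discriminating power.

Condition effects multiply proportions by $2^{LFC}$ (LFC
$\sim N(0,\sigma)$ on a random subset of non-phantom genera) followed by
renormalization; the pre-normalization LFC is recorded as ground truth.
Day 1 and day 35 get independent effect sets relative to the day-14
baseline (the tested day contrast is 35 vs 14); day effects are drawn
once and applied in both compartments, so the day contrast is consistent
whether pooled or stratified. One global seed drives everything, with
per-sample substreams derived deterministically from (seed, sample id)
by a string hash, so datasets are bit-reproducible and order-independent.

**What the simulator does not model** — and hence what passing tests do
not establish about real data: sequence-level errors, chimeras and OTU
clustering; contamination and host DNA; genome-size and 16S copy-number
variation as separate mechanisms (both are folded into $b_g$);
compositional correlations between genera (effects are independent);
and any taxonomy mismatch beyond the phantom set. Synthetic validation
shows the estimators recover what the model encodes; it cannot certify
the model itself.

## Numerical choices and degenerate inputs

* Skewness, correlation and regression refuse (flag or error) below 3
  usable genera; paired tests with zero-variance differences return the
  degenerate t (0 or $\pm\infty$) with an explicit flag.
* The filter threshold is a strict inequality: exactly 500,000 reads is
  retained.
* Dispersions are floored at $10^{-8}$; all-zero genera are flagged
  untestable and excluded from the BH burden.
* An exactly collinear pair yields a zero-width intercept interval
  rather than a warning.
* Bray–Curtis refuses all-zero sample rows by name; subsets in which a
  sample has no reads drop that sample from scoring and report it.
* Default problem sizes (400 genera, 78 pairs, 20–50 replicate
  simulations in the validation suites) keep a full run in seconds on a
  single core while leaving Monte-Carlo noise well inside the asserted
  margins.

## Known limitations

The engine is two-group only (no covariates, no likelihood-ratio
tests); exclusivity is exact-name based, so database synonymy leaks into
the exclusive sets; detection limits assume the log-log relation is
linear down to single reads, which truncation at count 1 bends for very
shallow pairs; and silhouette scores compare labellings, not clustering
methods — a low score means the labels do not match the distance
structure, not that structure is absent.
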