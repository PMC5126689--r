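---
title: "Two-stage lincRNA expression signatures: models and design choices"
author: "lincSignature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage lincRNA expression signatures: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis this package implements

Long intergenic non-coding RNAs (lincRNAs) are polyadenylated transcripts of
at least 200 nt arising from regions between protein-coding genes. Most are
expressed at low levels, in few samples, and in a highly tissue-restricted
way, which makes them attractive tumor biomarkers but statistically awkward:
expression matrices are sparse, effect sizes must survive two independent
cohorts to be believed, and the multiplicity correction must be honest about
the discreteness of rank-based tests on paired designs.

`lincSignature` implements the full two-stage signature workflow for paired
tumor/normal RNA-seq cohorts:

1. **Catalog filtering** — assembled transcripts are kept when they overlap a
   known lincRNA locus (>= 1 bp, strand-agnostic), are at least 200 nt long,
   and are not classified protein-coding (noncoding score below 0.5 removes a
   transcript; a missing score keeps it with a warning). Isoforms of one
   locus are collapsed by the arithmetic mean. A locus enters the analysis
   when its *calling rate* — the fraction of samples with FPKM >= 0.3, the
   conventional detectability threshold above background — is at least 20%.
   All four comparisons are inclusive, read literally off the stated
   inequalities.
2. **Discovery differential expression** — per-locus Wilcoxon signed-rank
   tests on paired tumor-minus-adjacent differences, mean-based log2 fold
   changes with a pseudocount of 0.1, Benjamini–Hochberg adjustment, and a
   permutation-based FDR estimate (below). A locus is selected when
   FC >= 2, BH p < 0.01, and its |statistic| clears the smallest threshold
   with estimated FDR < 1%.
3. **Replication** — TMM-normalized counts, negative-binomial log-link GLMs
   with age, race and sequencing-batch covariates, 1-df likelihood-ratio
   tests, and the replication rule |log2FC| >= 1 with p < 0.05 (relaxed
   variant 0.585, i.e. 1.5-fold), applied to tumor-vs-adjacent and
   tumor-vs-healthy-normal contrasts, plus direction concordance with the
   discovery stage.
4. **Regulatory context** — a TF–lincRNA bipartite network (edge iff a
   ChIP-seq peak falls within 2 kb upstream of the TSS through the TES), key
   TFs at degree >= 5, and a TF differential-expression filter
   (|log2FC| >= 0.585, BH p < 0.01).
5. **Neighbor co-expression** — nearest protein-coding partner per lincRNA
   (boundary-gap distance), orientation classes H2H/H2T/T2T, fold-change
   concordance by OLS, Spearman correlation against non-neighbor (> 1 Mb)
   and 1000 random-pair nulls, and a one-sided binomial test for
   head-to-head over-representation.
6. **Function inference** — per-lincRNA co-expressed coding gene sets at
   |rho| >= 0.4 (validated against a 1000-draw shuffled-pair null), followed
   by hypergeometric gene-set enrichment with BH adjustment. The
   hypergeometric route is the standard open equivalent of web-based
   annotation services and is labeled as such in outputs.
7. **Clinical association** — ER-subtype specificity by rank-sum contrasts,
   and median-split survival: Kaplan–Meier curves, log-rank tests and
   univariate Cox hazard ratios (via the `survival` package, the standard
   tool for this step).

# The permutation FDR estimator

For each locus the signed-rank statistic is standardized,
$Z = \sum_i \mathrm{sign}(d_i)\, r_i \big/ \sqrt{\sum_i r_i^2}$, where $d_i$
is the paired difference and $r_i$ the midrank of $|d_i|$ (zero differences
dropped). The null is generated by independently swapping the tumor/adjacent
labels within each pair. A label swap is exactly a sign flip of $d_i$ and
leaves the ranks of $|d_i|$ unchanged, so all $B$ permutation statistics are
obtained from one matrix product between the observed signed-rank matrix and
a random ±1 matrix — exact, fast, and bit-reproducible under a seed.

For a threshold $d$ on $|Z|$ the estimate is

$$\widehat{\mathrm{FDR}}(d) \;=\;
\frac{\tfrac1B\sum_{b=1}^{B} \#\{j : |Z_j^{(b)}| \ge d\}}
     {\#\{j : |Z_j| \ge d\}},$$

capped at 1, undefined (reported missing) when the denominator is zero. The
raw curve is a ratio of counts and can wiggle; we enforce monotone
non-increase in $d$ with a running minimum over ascending $d$. Selection
uses the smallest $d$ with $\widehat{\mathrm{FDR}}(d)$ below the target.
Because permuted statistics are standardized Rademacher sums regardless of
any true shift, loci with real effects inflate only the denominator, making
the estimator conservative on planted-truth simulations — the calibration
suite verifies that the realized false-discovery proportion at the 1% target
stays within 3% (three times nominal, absorbing Monte-Carlo error) across
50 simulated cohorts of 85 pairs and 500 loci at B = 200.

The test-identity question deserves a note: the paired design calls for the
Wilcoxon *signed-rank* test on differences, which is what we implement; the
exact null (all $2^n$ sign assignments) is used for n <= 25 without ties,
and a continuity-corrected normal approximation otherwise. The exact path is
verified against full enumeration for every n <= 10.

# The replication pathway

TMM factors follow the standard definition: per sample, log ratios (M) and
average log abundances (A) of library-normalized proportions against a
reference sample (the one whose upper-quartile fraction is closest to the
mean), genes zero in either sample excluded, 30% of M and 5% of A trimmed
from each tail, and the factor set to 2 to the inverse-variance-weighted
mean of the surviving M values, rescaled to geometric mean 1. The
implementation is authored here and cross-checked in the test suite against
the established count-analysis package, which agrees to machine precision.

Dispersions use a deliberately simple estimator: a per-locus
method-of-moments estimate of $\phi$ in $\mathrm{var} = \mu + \phi\mu^2$,
pooled across groups, floored at 0, and shrunk toward the common (median)
value with weight 0.3. This is a documented emulation of empirical-Bayes
moderation, not a reimplementation of it — it keeps every number auditable
while reproducing the qualitative behavior (Poisson limit, overdispersion
recovery) the tests assert. NB GLMs are fitted at fixed dispersion by
standard IRLS (`glm` with a negative-binomial family), with categorical
covariates one-hot via factor contrasts and age standardized; covariates
without variation in a contrast are dropped to keep the design full-rank.

# What the synthetic cohorts emulate

The generators define the study conditions; their defaults are fixed once
and are not tuned against test outcomes.

* **Annotation**: each lincRNA gets a designated protein-coding partner at a
  log-uniform gap (200 bp–100 kb) in a requested orientation, one pair per
  3 Mb block, so the partner is provably the nearest gene and decoys are
  > 1 Mb away. Orientation counts are apportioned by largest remainder, so
  a 14/37 head-to-head mix yields exactly 14 H2H pairs.
* **FPKM cohorts**: log-normal baselines, low for lincRNAs (meanlog log 2,
  sdlog 1.2) and higher for coding genes (meanlog log 20, sdlog 1.0);
  multiplicative log-normal sample noise (sdlog 0.4); planted log2 fold
  changes (default 10% of lincRNAs at |log2FC| = 3, 70% down-regulated,
  mirroring the observed predominance of down-regulation); dropout zeros on
  lincRNA rows (default 10%). Designated divergent pairs share a per-sample
  latent factor with loading chosen so the log-scale correlation equals the
  target (default 0.5); the coding partner of a planted-DE lincRNA inherits
  the effect scaled by that correlation, so fold-change concordance is
  planted alongside expression correlation. These distributions are our
  modeling choice: the real data motivate "low and sparse", not a specific
  family.
* **Count cohorts**: NB counts with mean = library size × relative abundance
  × 2^(planted log2FC in tumors) and dispersion 0.2; library sizes uniform
  on [5e5, 2e6]; random batch/age/race labels.
* **Peaks**: one 300 bp peak centered 1 kb upstream of the TSS per planted
  edge (jitter optional); decoy peaks at least 10 kb outside the window for
  non-edges.
* **Survival**: exponential event times with rate ratio equal to the target
  hazard ratio; independent exponential censoring with rate solved so the
  expected censored fraction equals the requested rate. The real curves
  imply no parametric family; exponential is the transparent choice.

What passing tests on these cohorts do **not** show: robustness to the
batch structure, GC/length biases, cellular heterogeneity and annotation
errors of real tumor data. The simulations validate the statistical
machinery, not the biology.

# Numerical and design choices

* Intervals are `GRanges` (1-based, closed) throughout; GTF and BED
  conversions are delegated to `rtracklayer`, so no manual coordinate
  arithmetic exists anywhere in the package.
* Boundary conventions: length 200 kept, score 0.5 kept, FPKM 0.3 called,
  calling rate 20% kept, degree 5 key, |rho| 0.4 co-expressed, |log2FC|
  gates inclusive; all p-value gates strict (< 0.01, < 0.05). Median-split
  ties go to the low group.
* Nearest-gene distance is the boundary gap, strand-ignored, 0 when
  overlapping; equidistant ties break to the lower-coordinate gene and are
  flagged. The head-to-head baseline proportion for the binomial test is
  computed from the input annotation's own orientation distribution, since
  no universal baseline exists.
* Orientation: same strand is head-to-tail; on opposite strands the pair is
  divergent (H2H) iff the leftmost feature is on the minus strand.
  Overlapping opposite-strand pairs are classified by the same rule.
  Flipping both strands maps H2H to T2T and back — the classifier is
  checked against this geometric truth table, and is symmetric in its two
  arguments.
* The permutation statistic is the standardized signed-rank Z; |log2FC|
  thresholds are deliberately not mixed into the permutation statistic so
  the FDR estimate calibrates a single quantity.
* One master seed expands to per-stage seeds by fixed offsets; every
  stochastic routine restores the caller's RNG state.
* Problem sizes in the shipped tests (e.g. 50 calibration cohorts of
  85 × 500 at B = 200; 200-rep type-I checks) are chosen to make
  Monte-Carlo bands tight enough to be meaningful while keeping the default
  suite quick to run; they are stated in each test.

# Known limitations

* The replication NB pathway is a simplified emulation: no quasi-likelihood,
  no robust dispersion, no exact tests. It is not a drop-in replacement for
  a production count-DE package and is labeled accordingly.
* The enrichment step is a plain hypergeometric over user-supplied sets; no
  ontology-graph propagation.
* `discoveryDE`'s fold change uses group means with a pseudocount; on
  heavily zero-inflated rows it is a coarse summary (the selection rule's
  rank test is unaffected by the pseudocount).
* Survival handling is univariate; no multivariable adjustment or competing
  risks.
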