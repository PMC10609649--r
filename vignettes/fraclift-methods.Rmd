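---
title: "Methods: size-fractionated community dynamics with fraclift"
author: "fraclift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-fractionated community dynamics with fraclift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraclift)
```

# The analysis problem

Marine bacterioplankton partition into two lifestyles: free-living (FL)
cells passing a 5 µm filter and retained on a 0.22 µm membrane, and
particle-attached (PA) cells retained on the 5 µm filter. When an algal
culture is exposed to a stressor — here a surfactin dose gradient over a
96 h cultivation — community composition shifts within and between the
two fractions. `fraclift` implements the downstream statistics for such
designs, starting from an OTU count table (OTU × sample), per-sample
design metadata, and a taxonomy table, held together in an
`OtuExperiment` (a `SummarizedExperiment` whose `counts` assay is the
single source of abundance truth).

All community-level statistics operate on per-sample relative abundances
or their Hellinger transform $\sqrt{n_{is}/N_s}$, which damps the
influence of dominant taxa and improves normality and homoscedasticity of
compositional data before ordination and permutation testing. Counts are
never silently modified: zero-depth samples, negative or non-integral
cells, and metadata mismatches are errors at load time, and rarefaction
(`rarefyCounts()`) is available but off by default — the indices below
are either depth-normalised already or explicitly depth-sensitive
(richness, Chao1), and subsampling discards data, so it is an explicit
user decision.

# Rarity and sensitivity classification

`classifyRarity()` applies the standard abundant / rare dichotomy over
all samples: an OTU is **abundant** when it reaches $\ge 1\%$ relative
abundance in at least one sample and is never below $0.01\%$ in any
sample; **rare** when it falls below $0.01\%$ somewhere and never
reaches $1\%$; every other OTU is labelled **intermediate** so the
three labels partition the OTU set. The explicit intermediate class
matters: with "never" clauses judged over all samples, most real tables
contain OTUs satisfying neither rule, and leaving them unlabelled would
make downstream tallies ambiguous.

`detectSensitiveOtus()` flags OTUs whose mean relative abundance in one
cultivation period differs from another period by more than a factor
`fold` (default 10 — equivalently, below 0.1×; the maximum pairwise
ratio covers both directions symmetrically). Choices the rule leaves
open, and how this package resolves them:

* **Stratification.** Ratios are compared within fraction × treatment
  strata by default (`stratifyBy`), because pooling fractions would mix
  the very lifestyle shift under study into the period contrast.
  Pooled or custom stratifications are one argument away.
* **Pairwise maximum, not one-vs-rest.** The contrast is the maximum
  over ordered period pairs of the ratio of period means. This is the
  strictest reading consistent with "one period changed more than 10
  times compared with other periods", and it makes the rule monotone:
  raising `fold` can only shrink the sensitive set.
* **Zeros.** A pseudo-abundance $\varepsilon = 10^{-6}$ (roughly one
  read in the deepest realistic sample) is added to numerator and
  denominator. OTUs that vanish at a period are the rule's motivating
  case, so they must produce finite, large ratios rather than errors.
* **Detection requirement.** An OTU must carry reads in at least two
  distinct periods to be called sensitive; an OTU seen once cannot
  exhibit a period change, only presence/absence.

`sensitiveHeatmapMatrix()` prepares the conventional visualisation:
$\log_{10}(\text{relative abundance} + \varepsilon)$ for sensitive OTUs,
columns ordered by fraction, treatment, period, rows annotated with the
rarity class.

# The particle-association niche (PAN) index

With FL samples scored 0 and PA samples scored 1, the PAN index of OTU
$i$ is the abundance-weighted mean of sample scores,

$$\mathrm{PAN}_i \;=\; \frac{\sum_s w_{is}\,[\mathrm{fraction}_s =
\mathrm{PA}]}{\sum_s w_{is}} \in [0, 1],$$

so an OTU occurring only in PA samples scores 1, only in FL samples 0,
and one equally represented in both fractions 0.5. Two decisions:

* **Weights.** `weight = "relative"` (default) uses per-sample relative
  abundances, so a deeply sequenced sample cannot dominate the mean;
  `weight = "raw"` uses read counts. The raw mode is also the exact
  estimator of the generator's allocation probability (below), because
  binomial thinning makes total PA reads / total reads an unbiased
  estimate of $\pi_i$.
* **Sequence filter.** Only OTUs with more than `minSequences` (default
  10) total reads in the analysed sample set are scored; an index
  estimated from a handful of reads is dominated by sampling noise. The
  filter applies to the subset actually analysed, so per-group
  computations (`taxonPanSummary(..., groupBy =)`) re-apply it within
  each group.

`taxonPanSummary()` aggregates OTU-level indices to a taxonomy rank per
rarity class (mean ± standard error $s/\sqrt{n}$, zero for singleton
taxa), and `lifestyleShift()` tracks taxon-level mean PAN across
cultivation periods, classifying each taxon as shifting "toward PA" or
"toward FL" by the sign of the least-squares slope of mean PAN on time.

# Alpha diversity and the ANOVA screen

`alphaDiversity()` computes, per sample: richness $S$; Shannon–Wiener
$H = -\sum p_i \log p_i$ (natural log by default, base 2 via `logBase`
for compatibility with older QIIME outputs); Simpson's index in both
forms — dominance $D = \sum p_i^2$ (the default headline column, the
form whose magnitudes sit near 0.2 when $H \approx 2.2$) and diversity
$1 - D$; Pielou evenness $J = H/\log S$ (undefined at $S = 1$); and
Chao1. Chao1 defaults to the bias-corrected form
$S + F_1(F_1 - 1)/(2(F_2 + 1))$, which stays finite when no doubletons
are observed; the classic $S + F_1^2/(2F_2)$ is available for
comparison. When $F_1 = 0$, both reduce to $S$.

`diversityAnova()` screens each index against each design factor with a
classical one-way ANOVA (`stats::aov`). The algal-cell change is a
continuous covariate (cells/mL per 24 h, undefined at 0 h); a one-way
screen needs groups, so it is binned by sign into decline / stable /
increase. The binning threshold (`stableTol`, default 0) is exposed
because "stable" is operationally a measurement-noise band. The
degenerate all-identical-response case returns $F = 0$, $p = 1$ rather
than NaN.

# Community inference

`brayCurtis()` computes $d(a,b) = \sum_i |x_{ia} - x_{ib}| / \sum_i
(x_{ia} + x_{ib})$ between sample columns, by default on
Hellinger-transformed counts when given an `OtuExperiment` (matching the
package-wide transform policy); a pair of all-zero profiles has no
defined dissimilarity and errors.

`nmds()` is a non-metric MDS built from the two standard ingredients:
monotone (isotonic) regression of configuration distances on the
dissimilarity rank order — primary tie handling, ties broken by current
configuration distance before the pool-adjacent-violators fit — and the
Guttman majorization update towards the fitted disparities. Stress is
Kruskal's stress-1, $\sqrt{\sum(d - \hat d)^2 / \sum d^2}$. The first
start is the classical metric MDS solution (`cmdscale`), followed by
random restarts (default 20, seed required); the lowest-stress
configuration wins, iterating until the stress change falls below
`tol = 10^{-6}` or `maxIter = 500`. Ordinations with stress $\ge 0.20$
are flagged as unreliable, the conventional interpretability cut-off.

`permanova()` partitions the squared dissimilarities for a single
factor: $SS_T = \sum_{i<j} d_{ij}^2/n$, $SS_W = \sum_g \sum_{i<j \in g}
d_{ij}^2/n_g$, pseudo-$F = (SS_A/(a-1))/(SS_W/(n-a))$,
$R^2 = SS_A/SS_T$. One-factor tests mirror the convention of reporting
each design factor separately; multi-factor partitions are out of scope.
`anosim()` provides the rank-based analogue
$R = (\bar r_B - \bar r_W)/(M/2)$, the statistic conventionally called a
"global R" — both are reported because published tables are not always
explicit about which statistic a "global R" denotes. Both tests permute
sample labels only, use $p = (1 + \#\{ \text{perm} \ge \text{obs}
\})/(1 + n_\mathrm{perm})$ with default 999 permutations (so the
smallest attainable $p$ is 0.001), and require an explicit seed, making
every p-value bit-reproducible.

# The synthetic community generator

`simulateCommunity()` provides ground-truthed data with the statistical
structure the analysis assumes. Its defaults define the study
conditions; they are chosen once, on domain grounds, and documented
here:

* **Design.** One FL and one PA sample per (treatment, period,
  replicate) cell: a control followed at 0, 24, 48, 72, 96 h and 0 and
  2 mg/L surfactin at 24–96 h (the pre-treatment 0 h state is covered
  by the control), plus 3 mg/L at 24 h only — 28 samples at the default
  single replicate, matching the deposited sample count of the
  motivating design.
* **Depths.** Target depths are drawn uniformly from 10,819–94,695
  reads per sample, the observed range of the motivating dataset; only
  the range is known, so uniform is the least-informative choice. A
  pair's total is the sum of its two targets; the realised split
  between FL and PA follows the allocation model, so realised per-sample
  depths scatter around the targets.
* **Abundances.** Baseline relative abundances are log-normal with
  $\sigma = 2$, giving the few-abundant / many-rare skew of 16S OTU
  tables (at 300 OTUs, a handful reach percent-level abundance while
  most sit below 0.1%).
* **Overdispersion.** Pair-level compositions are Dirichlet with
  concentration 2000 around the expected composition, then multinomial
  at the pair depth. Concentration 2000 yields a replicate-level CV of
  roughly 20% for a 1%-abundance OTU — the magnitude reported for
  well-controlled 16S replicates — without swamping genuine period
  effects at the single-replicate design.
* **Lifestyle shift.** Each OTU carries an allocation logit
  $\beta_{0i} \sim N(-0.6, 0.8)$; its reads fall in the PA sample of a
  pair with probability $\pi_i(c, t) = \mathrm{logistic}(\beta_{0i} +
  s\,c\,t)$, dose $c$ in mg/L, time $t$ in days, slope $s = 0.125$
  logit/(mg/L·day). The negative $\beta_0$ mean makes most taxa prefer
  the FL fraction at baseline (taxon mean PAN below 0.5), and the slope
  moves the average OTU from $\pi \approx 0.35$ towards $\pi \approx
  0.6$ over four days at 2 mg/L — a visible but not saturating shift.
  Binomial thinning of each OTU's pair total was chosen over separate
  per-fraction draws precisely so that $\pi_i(c,t)$ is the exact
  expected PA mass share, giving parameter-recovery tests a sharp
  target.
* **Sensitive OTUs.** `injectSensitiveOtus()` multiplies (or divides,
  with probability ½) the expected relative abundance of $k$ chosen
  OTUs by `fold` at one random period, recording the flags. Effects
  enter the expected composition before renormalisation, so an
  injection leaves relative contrasts between unaffected OTUs intact up
  to the (small) renormalisation factor.
* **Covariate.** The algal-cell change is simulated as a
  dose-dependent trend (growth at 0 mg/L, increasingly negative change
  at 2–3 mg/L, near zero in the algae-free control) with Gaussian
  noise, and is undefined at 0 h. No algal growth model is implied;
  the covariate exists so the ANOVA screen has its fourth factor.

What the generator does **not** emulate: taxonomic label realism (class
tokens are partitioned by configurable weights, not ecology), phylogenetic
structure, temporal autocorrelation of the community beyond the injected
effects, chimeras/contamination, and compositional artefacts of PCR or
primer bias. Tests passing on this generator therefore demonstrate that
the statistics recover known structure from realistically noisy,
realistically skewed fraction-split count data — not that any biological
conclusion about real communities is reproduced.

# Problem sizes and numerical choices in the test suite

The suite exercises: oracle equivalence of the classifiers, the PAN
index, and ANOSIM against literal loop implementations on random 20–50
OTU × 8–12 sample tables at tolerance $10^{-12}$; PERMANOVA type-I
error over 1000 null simulations (10 samples, 2 groups, 199
permutations), accepted at $0.05 \pm 0.02$; sensitive-OTU recovery over
20 simulation replicates of the 28-sample default design with 15
injected 20-fold effects per replicate (sensitivity $\ge 0.9$,
false-positive rate $\le 0.05$ among abundant OTUs); allocation-logit
recovery within $\pm 0.05$ for OTUs with more than 1000 reads; and NMDS
stress within 0.02 of vegan's multi-start `metaMDS` on random 15-sample
dissimilarity matrices. These sizes keep each property estimable with
comfortable margins while the full suite runs in well under a coffee
break.

# Known limitations

* PERMANOVA and ANOSIM are one-factor with unrestricted permutations;
  nested or sequential multi-factor designs are not provided.
* The sensitive-OTU rule is a fold-change screen, not an inferential
  test: it has no error model, and its $\varepsilon$ makes calls near
  the detection limit threshold-dependent by construction.
* PAN indices from few samples per group are noisy; the
  `minSequences` filter bounds read-level noise but not sample-level
  confounding (e.g. a taxon present only late in a shifting design).
* The generator's fraction split is conditionally independent across
  OTUs given the pair composition; real particle colonisation is
  spatially aggregated, so real PA counts are likely more overdispersed
  than the model's.
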