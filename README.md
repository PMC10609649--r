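# fraclift

Community-dynamics analysis for **size-fractionated bacterioplankton**:
OTU tables split into free-living (FL, 0.22–5 µm) and particle-attached
(PA, > 5 µm) fractions, sampled along an experimental gradient such as a
surfactin dose over a 96 h algal cultivation. The package is aimed at
microbial ecologists who have a 16S OTU count table, per-sample design
metadata, and a taxonomy table, and want the fraction-aware downstream
statistics in one tested, scriptable place.

## What it computes

Data live in an `OtuExperiment` (a `SummarizedExperiment` subclass;
counts assay + colData design + rowData taxonomy). On top of it:

* **Rarity classification** — abundant (reaches ≥ 1 % in some sample,
  never < 0.01 %), rare (< 0.01 % somewhere, never ≥ 1 %), intermediate
  (the remainder); the three labels partition the OTU set.
* **Sensitive OTUs** — OTUs whose period mean relative abundance changes
  more than 10-fold (or below 0.1×) between cultivation periods within a
  fraction × treatment stratum, with a log10 heatmap matrix for display.
* **PAN index** — the particle-association niche index, the
  abundance-weighted mean of 0/1 fraction scores per OTU:
  `PAN_i = Σ_s w_is · [fraction_s = PA] / Σ_s w_is ∈ [0, 1]`
  (PA-only OTU → 1, FL-only → 0, balanced → 0.5), plus taxon-level
  mean ± s.e. summaries and lifestyle-shift trajectories over time.
* **Alpha diversity** — richness, Shannon–Wiener *H*, Simpson (dominance
  *D* and 1 − *D*), Pielou evenness, Chao1 (bias-corrected or classic),
  with a one-way ANOVA screen against the design factors.
* **Community inference** — Bray–Curtis dissimilarities on
  Hellinger-transformed counts, non-metric MDS (isotonic regression +
  Guttman majorization, Kruskal stress-1, multi-start, stress ≥ 0.20
  flagged), and permutation tests: PERMANOVA (R², pseudo-F) and ANOSIM
  (global R), both seed-reproducible.
* **Synthetic communities** — a Dirichlet-multinomial generator with a
  log-normal abundance skew, uniform 10,819–94,695 read depths, and a
  dose × time lifestyle shift `π_i(c, t) = logistic(β0_i + s·c·t)`
  controlling each OTU's PA allocation, with full ground truth for
  recovery experiments (`injectSensitiveOtus()` adds known fold-change
  effects).

## Worked example

```r
library(fraclift)

sim <- simulateCommunity(simulationConfig(seed = 7))
oe <- sim$experiment
oe
#> OtuExperiment: 300 OTUs x 28 samples
#>   fractions: FL = 14 , PA = 14
#>   read depth: 43077-107671
#>   colData: treatment, dose, period, replicate, pair_id, algal_cell_change, sample_id

table(classifyRarity(oe)$label)
#>     abundant         rare intermediate
#>           37          188           75

pans <- panIndex(oe)               # relative-abundance weights, > 10 reads
round(summary(pans$pan), 3)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.085   0.270   0.379   0.399   0.513   0.821

taxonPanSummary(oe)[1:2, ]         # taxon-level mean ± s.e. per rarity class
#>                 taxon   rarity group  mean_pan     se_pan n_otus
#> 1      Actinobacteria abundant   all 0.4884898 0.04885926      6
#> 2 Alphaproteobacteria abundant   all 0.4141292 0.06396851      9

d <- brayCurtis(oe)                # Hellinger-transformed counts
nmds(d, seed = 7)
#> NMDS (k = 2): stress = 0.0490 (acceptable < 0.20), 20 restart(s)

permanova(d, sampleFractions(oe), nPermutations = 999, seed = 7)
#> PERMANOVA: R2 = 0.4705, pseudo-F = 23.1051, p = 0.001 (999 permutations)

anosim(d, sampleFractions(oe), nPermutations = 999, seed = 7)
#> ANOSIM: R = 0.9999, R = 0.9999, p = 0.001 (999 permutations)
```

Reading the output: most of the simulated community's PAN mass sits
below 0.5 (median 0.379), i.e. a free-living preference at baseline; the
fraction factor separates communities strongly (PERMANOVA R² = 0.47 at
the permutation floor p = 0.001, ANOSIM R ≈ 1), and the two-dimensional
ordination is trustworthy (stress 0.049, well under the 0.20 cut-off).

The methods vignette (`vignettes/fraclift-methods.Rmd`) documents the
statistical choices: ratio conventions of the sensitivity rule, PAN
weighting, Simpson/Chao1 variants, NMDS internals, and exactly what the
generator does and does not emulate.

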