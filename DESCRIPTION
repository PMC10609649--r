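Package: fraclift
Title: Size-Fractionated Bacterioplankton Community Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of size-fractionated (free-living versus
    particle-attached) bacterioplankton OTU tables: abundant/rare/intermediate
    rarity classification, fold-change detection of period-sensitive OTUs, the
    particle-association niche (PAN) index with taxon-level summaries, alpha
    diversity (Shannon-Wiener, Simpson, Pielou evenness, Chao1) with one-way
    ANOVA screens, and community-composition inference from Bray-Curtis
    dissimilarities (non-metric multidimensional scaling with Kruskal stress,
    PERMANOVA and ANOSIM with permutation p-values). Includes a
    Dirichlet-multinomial generator for size-fractionated communities with a
    treatment- and time-dependent lifestyle shift and known ground truth, for
    recovery experiments. Data are held in an OtuExperiment container
    extending SummarizedExperiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, yaml
Suggests: testthat (>= 3.0.0), vegan, pheatmap, jsonlite, withr, knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Software, Sequencing
RoxygenNote: 7.3.3
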