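# 2 FL + 2 PA samples; rows exercise the PAN boundary cases.
panFixture <- function() {
    counts <- rbind(
        paOnly = c(0L, 0L, 12L, 8L),
        flOnly = c(10L, 10L, 0L, 0L),
        equal = c(15L, 15L, 15L, 15L),
        skewed = c(30L, 0L, 0L, 90L),
        shallow = c(3L, 2L, 1L, 0L),   # <= 10 reads: omitted
        filler = c(942L, 973L, 972L, 887L))
    colnames(counts) <- c("fl1", "fl2", "pa1", "pa2")
    toyExperiment(counts, fraction = c("FL", "FL", "PA", "PA"))
}

test_that("PAN boundary cases: PA-only 1, FL-only 0, equal split 0.5", {
    pans <- panIndex(panFixture())
    p <- setNames(pans$pan, pans$otu_id)
    expect_identical(p[["paOnly"]], 1)
    expect_identical(p[["flOnly"]], 0)
    # equal counts at equal depths: identical relative abundance in
    # every FL and PA sample of a balanced design
    expect_identical(p[["equal"]], 0.5)
    expect_false("shallow" %in% pans$otu_id)
    expect_equal(pans$n_samples_present[pans$otu_id == "paOnly"], 2)
})

test_that("PAN is the abundance-weighted mean of the 0/1 fraction scores", {
    # one FL sample at weight 0.01, one PA at 0.03 -> 0.03/0.04 = 0.75
    counts <- rbind(target = c(10L, 30L), other = c(990L, 970L))
    colnames(counts) <- c("fl", "pa")
    oe <- toyExperiment(counts, fraction = c("FL", "PA"))
    pans <- panIndex(oe)
    expect_equal(pans$pan[pans$otu_id == "target"], 0.75,
                 tolerance = 1e-12)
})

test_that("PAN equals the loop-based oracle in both weight modes", {
    for (seed in c(41, 42, 43)) {
        cts <- skewedCounts(20, 8, seed = seed, depth = 5000L)
        fr <- rep(c("FL", "PA"), 4)
        oe <- toyExperiment(cts, fraction = fr)
        for (w in c("relative", "raw")) {
            pans <- panIndex(oe, weight = w)
            ora <- oraclePan(cts, fr, weight = w)
            expect_equal(setNames(pans$pan, pans$otu_id), ora,
                         tolerance = 1e-12)
        }
    }
})

test_that("PAN invariants: range, duplication, depth, and mirror symmetry", {
    cts <- skewedCounts(25, 6, seed = 44, depth = 8000L)
    fr <- c("FL", "PA", "FL", "PA", "FL", "PA")
    oe <- toyExperiment(cts, fraction = fr)
    pans <- panIndex(oe, minSequences = 0)  # full OTU set for invariants
    expect_true(all(pans$pan >= 0 & pans$pan <= 1))
    # duplicating every sample leaves the index unchanged
    cts2 <- cbind(cts, cts)
    colnames(cts2) <- paste0("s", seq_len(ncol(cts2)))
    dup <- panIndex(toyExperiment(cts2, fraction = c(fr, fr)),
                    minSequences = 0)
    expect_equal(dup$pan, pans$pan, tolerance = 1e-12)
    # relative weights: immune to resequencing one sample 5x deeper
    deeper <- cts; deeper[, 1] <- deeper[, 1] * 5L
    expect_equal(panIndex(toyExperiment(deeper, fraction = fr),
                          minSequences = 0)$pan,
                 pans$pan, tolerance = 1e-12)
    # swapping FL and PA labels mirrors the index
    swapped <- panIndex(toyExperiment(cts,
        fraction = c("PA", "FL", "PA", "FL", "PA", "FL")),
        minSequences = 0)
    expect_equal(swapped$pan + pans$pan, rep(1, nrow(pans)),
                 tolerance = 1e-12)
})

test_that("single-fraction designs degenerate with a warning", {
    cts <- randomCounts(8, 4, seed = 45)
    oe <- toyExperiment(cts, fraction = "FL")
    expect_warning(pans <- panIndex(oe), "one fraction")
    expect_true(all(pans$pan == 0))
})

test_that("taxon summaries aggregate member OTU PAN values with s.e.", {
    cts <- rbind(
        a1 = c(2L, 2L, 40L, 40L), a2 = c(20L, 20L, 30L, 30L),
        a3 = c(30L, 30L, 20L, 20L), b1 = c(50L, 50L, 50L, 50L),
        filler = c(898L, 898L, 860L, 860L))
    colnames(cts) <- c("fl1", "fl2", "pa1", "pa2")
    md <- data.frame(sample_id = colnames(cts),
                     fraction = c("FL", "FL", "PA", "PA"))
    tax <- data.frame(otu_id = rownames(cts),
        class = c("TaxA", "TaxA", "TaxA", "TaxB", "TaxC"))
    oe <- OtuExperiment(cts, md, taxonomy = tax)
    rar <- classifyRarity(oe, upper = 0.001, lower = 1e-6)
    pans <- panIndex(oe)
    pv <- setNames(pans$pan, pans$otu_id)
    ts <- taxonPanSummary(oe, rarity = rar)
    a <- ts[ts$taxon == "TaxA", ]
    expect_equal(a$n_otus, 3L)
    expect_equal(a$mean_pan, mean(pv[c("a1", "a2", "a3")]),
                 tolerance = 1e-12)
    expect_equal(a$se_pan, sd(pv[c("a1", "a2", "a3")]) / sqrt(3),
                 tolerance = 1e-12)
    b <- ts[ts$taxon == "TaxB", ]
    expect_equal(b$n_otus, 1L)
    expect_identical(b$se_pan, 0)  # singleton taxon
    expect_equal(b$mean_pan, pv[["b1"]], tolerance = 1e-12)
})

test_that("hand arithmetic: PAN values (0.2, 0.4, 0.6) summarise to 0.4 +/- 0.1155", {
    vals <- c(0.2, 0.4, 0.6)
    expect_equal(mean(vals), 0.4)
    expect_equal(sd(vals) / sqrt(3), 0.11547005, tolerance = 1e-7)
})

test_that("positive lifestyle-shift slopes are recovered as 'toward PA'", {
    cfg <- simulationConfig(nOtus = 150, seed = 46, panShiftSlope = 0.35,
        treatments = c(S2 = 2), periods = list(S2 = c(0, 24, 48, 72, 96)),
        nReplicates = 2)
    sim <- simulateCommunity(cfg)
    shift <- lifestyleShift(sim$experiment, weight = "raw")
    per_taxon <- unique(as.data.frame(shift)[, c("taxon", "slope",
                                                 "direction")])
    big <- per_taxon$taxon %in%
        names(which(table(sim$truth$class) >= 10))
    expect_true(all(per_taxon$direction[big] == "toward PA"))
    # trajectory rises monotonically for well-populated taxa
    sh <- as.data.frame(shift)
    for (tx in per_taxon$taxon[big]) {
        tr <- sh$mean_pan[sh$taxon == tx][order(sh$period[sh$taxon == tx])]
        expect_gt(tr[length(tr)], tr[1])
    }
})

test_that("a zero shift slope leaves taxon trajectories flat", {
    cfg <- simulationConfig(nOtus = 150, seed = 47, panShiftSlope = 0,
        treatments = c(S2 = 2), periods = list(S2 = c(0, 24, 48, 72, 96)),
        nReplicates = 2)
    sim <- simulateCommunity(cfg)
    shift <- lifestyleShift(sim$experiment, weight = "raw")
    sh <- as.data.frame(shift)
    big <- names(which(table(sim$truth$class) >= 15))
    expect_true(all(abs(sh$delta_from_first[sh$taxon %in% big]) < 0.1))
    # FL preference (beta0 < 0 on average) shows as mean PAN < 0.5
    expect_lt(mean(sh$mean_pan[sh$taxon %in% big]), 0.5)
})
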