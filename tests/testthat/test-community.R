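test_that("Bray-Curtis reproduces its defining arithmetic", {
    expect_equal(as.numeric(brayCurtis(cbind(a = c(1, 1, 0),
                                             b = c(0, 1, 1)))), 0.5)
    m <- cbind(a = c(2, 3, 1), b = c(2, 3, 1))
    expect_equal(as.numeric(brayCurtis(m)), 0)
    disjoint <- cbind(a = c(1, 2, 0, 0), b = c(0, 0, 3, 4))
    expect_equal(as.numeric(brayCurtis(disjoint)), 1)
    expect_error(brayCurtis(cbind(a = c(0, 0), b = c(0, 0))), "all-zero")
    expect_error(brayCurtis(cbind(a = c(-1, 2), b = c(1, 1))),
                 "non-negative")
})

test_that("Bray-Curtis matches vegan and is depth-invariant on proportions", {
    skip_if_not_installed("vegan")
    cts <- skewedCounts(30, 9, seed = 71, depth = 4000L)
    rel <- relativeAbundance(cts)
    d <- brayCurtis(rel)
    ref <- vegan::vegdist(t(rel), method = "bray")
    expect_equal(as.numeric(d), as.numeric(ref), tolerance = 1e-12)
    # normalised profiles: resequencing a sample deeper changes nothing
    deep <- cts; deep[, 4] <- deep[, 4] * 11L
    expect_equal(as.numeric(brayCurtis(relativeAbundance(deep))),
                 as.numeric(d), tolerance = 1e-12)
    expect_true(all(as.numeric(d) >= 0 & as.numeric(d) <= 1))
})

test_that("NMDS embeds planar configurations with near-zero stress", {
    set.seed(72)
    X <- matrix(rnorm(20), 10, 2)
    fit <- nmds(dist(X), seed = 73, nRestarts = 5)
    expect_lt(nmdsStress(fit), 0.01)
    expect_true(fit@converged)
    expect_equal(colMeans(nmdsScores(fit)), c(0, 0), tolerance = 1e-8)
})

test_that("NMDS stress is invariant to rotation and reflection of the input", {
    set.seed(74)
    X <- matrix(rnorm(24), 12, 2)
    theta <- 0.7
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    d1 <- dist(X)
    d2 <- dist(X %*% R %*% diag(c(1, -1)))
    expect_equal(nmdsStress(nmds(d1, seed = 75, nRestarts = 5)),
                 nmdsStress(nmds(d2, seed = 75, nRestarts = 5)),
                 tolerance = 1e-6)
})

test_that("NMDS separates simulated clusters and flags poor fits", {
    set.seed(76)
    centers <- rbind(c(0, 0, 0), c(6, 6, 6))
    X <- rbind(centers[rep(1, 8), ] + matrix(rnorm(24, sd = .5), 8),
               centers[rep(2, 8), ] + matrix(rnorm(24, sd = .5), 8))
    fit <- nmds(dist(X), seed = 77, nRestarts = 10)
    co <- nmdsScores(fit)
    within <- c(dist(co[1:8, ]), dist(co[9:16, ]))
    between <- as.vector(as.matrix(dist(co))[1:8, 9:16])
    frac <- mean(outer(within, between, FUN = "<"))
    expect_gt(frac, 0.9)
    # random (non-embeddable) dissimilarities warn at the 0.20 criterion
    set.seed(78)
    m <- matrix(runif(225), 15); m <- (m + t(m)) / 2; diag(m) <- 0
    expect_warning(bad <- nmds(as.dist(m), seed = 79, nRestarts = 5),
                   ">= 0.20")
    expect_gte(nmdsStress(bad), 0.20)
})

test_that("PERMANOVA recovers the univariate ANOVA decomposition", {
    # Euclidean distance on one variable: R2 must equal SS_among/SS_total
    set.seed(80)
    x <- c(rnorm(6), rnorm(6, 2))
    g <- rep(c("a", "b"), each = 6)
    res <- permanova(dist(x), g, nPermutations = 99, seed = 81)
    fit <- anova(lm(x ~ g))
    r2_ref <- fit$`Sum Sq`[1] / sum(fit$`Sum Sq`)
    expect_equal(effectSize(res), r2_ref, tolerance = 1e-10)
    expect_equal(testStatistic(res), fit$`F value`[1], tolerance = 1e-10)
})

test_that("PERMANOVA agrees with vegan::adonis2 and is seed-reproducible", {
    skip_if_not_installed("vegan")
    cts <- skewedCounts(40, 12, seed = 82, depth = 5000L)
    d <- brayCurtis(hellingerTransform(cts))
    g <- factor(rep(c("a", "b", "c"), each = 4))
    res <- permanova(d, g, nPermutations = 199, seed = 83)
    ref <- vegan::adonis2(d ~ g, permutations = 199)
    expect_equal(effectSize(res), ref$R2[1], tolerance = 1e-10)
    expect_equal(testStatistic(res), ref$F[1], tolerance = 1e-10)
    res2 <- permanova(d, g, nPermutations = 199, seed = 83)
    expect_identical(pValue(res), pValue(res2))
    expect_gte(pValue(res), 1 / 200)
})

test_that("maximal separation drives the permutation p to its floor", {
    # two tight, disjoint clusters of near-duplicate profiles; the
    # observed ordering beats every permutation that is not the exact
    # partition, which 999 draws from the 352716 partitions of 21
    # samples essentially never reproduce
    nA <- 10; nB <- 11
    profA <- sapply(seq_len(nA), function(k) c(5 + k * 1e-4, 1e-3, 0))
    profB <- sapply(seq_len(nB), function(k) c(0, 3 + k * 1e-4, 2))
    prof <- cbind(profA, profB)
    colnames(prof) <- paste0("s", seq_len(nA + nB))
    d <- brayCurtis(prof)
    g <- rep(c("x", "y"), c(nA, nB))
    res <- permanova(d, g, nPermutations = 999, seed = 84)
    expect_equal(pValue(res), 1 / 1000)
    an <- anosim(d, g, nPermutations = 999, seed = 84)
    expect_equal(effectSize(an), 1)
    expect_equal(pValue(an), 1 / 1000)
})

test_that("ANOSIM matches the brute-force rank oracle, ties included", {
    for (seed in c(85, 86)) {
        cts <- skewedCounts(15, 8, seed = seed, depth = 300L)
        d <- brayCurtis(relativeAbundance(cts))
        g <- rep(c("a", "b"), each = 4)[seq_len(attr(d, "Size"))]
        res <- anosim(d, g, nPermutations = 49, seed = seed)
        expect_equal(effectSize(res),
                     oracleAnosimR(as.matrix(d), g), tolerance = 1e-12)
    }
    # duplicated distances force ties; average ranks must be used
    m <- matrix(c(0, 1, 2, 2,
                  1, 0, 2, 2,
                  2, 2, 0, 1,
                  2, 2, 1, 0), 4)
    g <- c("a", "a", "b", "b")
    res <- anosim(as.dist(m), g, nPermutations = 23, seed = 87)
    expect_equal(effectSize(res), oracleAnosimR(m, g), tolerance = 1e-12)
})

test_that("ANOSIM R sits near zero under random labels, one under separation", {
    skip_if_not_installed("vegan")
    set.seed(88)
    cts <- skewedCounts(30, 10, seed = 88, depth = 2000L)
    d <- brayCurtis(relativeAbundance(cts))
    g <- sample(rep(c("a", "b"), 5))
    res <- anosim(d, g, nPermutations = 199, seed = 89)
    expect_lt(abs(effectSize(res)), 0.35)
    ref <- vegan::anosim(d, g, permutations = 0)
    expect_equal(effectSize(res), unname(ref$statistic),
                 tolerance = 1e-10)
})

test_that("PERMANOVA power rises monotonically with effect size", {
    shiftRate <- function(shift, nsim = 60) {
        rej <- 0L
        for (i in seq_len(nsim)) {
            set.seed(9000 + i)
            base <- rexp(30)
            shifted <- base * exp(shift * rnorm(30))
            cts <- cbind(
                sapply(1:5, function(j) rmultinom(1, 2000, base)),
                sapply(1:5, function(j) rmultinom(1, 2000, shifted)))
            rownames(cts) <- paste0("o", 1:30)
            colnames(cts) <- paste0("s", 1:10)
            d <- brayCurtis(hellingerTransform(cts))
            p <- pValue(permanova(d, rep(c("a", "b"), each = 5),
                                  nPermutations = 99, seed = 9000 + i))
            if (p <= 0.05) rej <- rej + 1L
        }
        rej / nsim
    }
    rates <- vapply(c(0, 0.5, 1.5), shiftRate, numeric(1))
    expect_lte(rates[1], rates[2])
    expect_lte(rates[2], rates[3])
    expect_gt(rates[3], 0.8)
})
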