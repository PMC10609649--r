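# Builders for small in-code fixtures.

# OtuExperiment from a count matrix; fractions/treatments/periods recycled
# across samples.
toyExperiment <- function(counts, fraction, treatment = "S0", period = 0,
                          replicate = 1L) {
    md <- data.frame(
        sample_id = colnames(counts),
        fraction = rep_len(fraction, ncol(counts)),
        treatment = rep_len(treatment, ncol(counts)),
        period = rep_len(period, ncol(counts)),
        replicate = rep_len(replicate, ncol(counts)))
    OtuExperiment(counts, md)
}

randomCounts <- function(nOtu, nSample, seed, lambda = 30) {
    set.seed(seed)
    m <- matrix(rpois(nOtu * nSample, lambda), nOtu, nSample,
                dimnames = list(sprintf("OTU%03d", seq_len(nOtu)),
                                sprintf("s%02d", seq_len(nSample))))
    # ensure positive depths
    m[1L, colSums(m) == 0] <- 1L
    storage.mode(m) <- "integer"
    m
}

# Skewed random table: log-normal expected abundances, multinomial reads.
skewedCounts <- function(nOtu, nSample, seed, depth = 20000L, sigma = 2) {
    set.seed(seed)
    base <- rlnorm(nOtu, sdlog = sigma)
    m <- sapply(seq_len(nSample), function(j)
        rmultinom(1L, depth, base)[, 1L])
    dimnames(m) <- list(sprintf("OTU%03d", seq_len(nOtu)),
                        sprintf("s%02d", seq_len(nSample)))
    keep <- colSums(m) > 0
    storage.mode(m) <- "integer"
    m[, keep, drop = FALSE]
}

# Exhaustive rule-based oracles, written as literal loops so they stay
# independent of the vectorised implementations they check.

oracleRarity <- function(counts, upper = 0.01, lower = 1e-4) {
    rel <- apply(counts, 2L, function(col) col / sum(col))
    out <- character(nrow(counts))
    for (i in seq_len(nrow(counts))) {
        reaches_upper <- FALSE
        ever_below_lower <- FALSE
        ever_at_upper <- FALSE
        for (j in seq_len(ncol(counts))) {
            if (rel[i, j] >= upper) ever_at_upper <- TRUE
            if (rel[i, j] >= upper) reaches_upper <- TRUE
            if (rel[i, j] < lower) ever_below_lower <- TRUE
        }
        out[i] <- if (reaches_upper && !ever_below_lower) "abundant"
        else if (ever_below_lower && !ever_at_upper) "rare"
        else "intermediate"
    }
    out
}

oraclePan <- function(counts, fraction, minSequences = 10,
                      weight = "relative") {
    rel <- apply(counts, 2L, function(col) col / sum(col))
    w <- if (weight == "relative") rel else counts
    pan <- setNames(rep(NA_real_, nrow(counts)), rownames(counts))
    for (i in seq_len(nrow(counts))) {
        if (sum(counts[i, ]) <= minSequences) next
        num <- 0; den <- 0
        for (j in seq_len(ncol(counts))) {
            sc <- if (fraction[j] == "PA") 1 else 0
            num <- num + w[i, j] * sc
            den <- den + w[i, j]
        }
        pan[i] <- num / den
    }
    pan[!is.na(pan)]
}

oracleSensitive <- function(counts, meta, fold = 10, eps = 1e-6) {
    rel <- apply(counts, 2L, function(col) col / sum(col))
    strata <- unique(paste(meta$fraction, meta$treatment))
    flagged <- setNames(rep(FALSE, nrow(counts)), rownames(counts))
    for (st in strata) {
        in_st <- paste(meta$fraction, meta$treatment) == st
        pers <- unique(meta$period[in_st])
        if (length(pers) < 2L) next
        for (i in seq_len(nrow(counts))) {
            means <- sapply(pers, function(p)
                mean(rel[i, in_st & meta$period == p]))
            for (a in seq_along(pers)) for (b in seq_along(pers))
                if ((means[a] + eps) / (means[b] + eps) > fold)
                    flagged[i] <- TRUE
        }
    }
    detected2 <- sapply(seq_len(nrow(counts)), function(i)
        length(unique(meta$period[counts[i, ] > 0])) >= 2L)
    names(flagged)[flagged & detected2]
}

oracleAnosimR <- function(D, groups) {
    n <- nrow(D)
    vals <- c(); within <- c()
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        vals <- c(vals, D[i, j])
        within <- c(within, groups[i] == groups[j])
    }
    rk <- rank(vals)
    M <- length(vals)
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}
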