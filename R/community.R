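#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(a, b) = \sum_i |x_{ia} - x_{ib}| / \sum_i (x_{ia} + x_{ib})},
#' computed between columns. Profiles are typically
#' Hellinger-transformed counts ([hellingerTransform()]) or relative
#' abundances; on depth-normalised profiles the distance is invariant to
#' sequencing depth. A pair of all-zero samples has no defined
#' dissimilarity and is an error.
#'
#' @param profiles numeric matrix with samples in columns and
#'   non-negative entries, or an [OtuExperiment-class] (whose counts are
#'   Hellinger-transformed first).
#' @return a \code{stats::dist} object with entries in [0, 1].
#' @examples
#' brayCurtis(cbind(a = c(1, 1, 0), b = c(0, 1, 1)))  # 0.5
#' @export
brayCurtis <- function(profiles) {
    if (methods::is(profiles, "OtuExperiment"))
        profiles <- hellingerTransform(profiles)
    if (any(profiles < 0))
        stop("profiles must be non-negative")
    n <- ncol(profiles)
    if (n < 2L)
        stop("need >= 2 samples")
    d <- matrix(0, n, n, dimnames = list(colnames(profiles),
                                         colnames(profiles)))
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
        tot <- sum(profiles[, a] + profiles[, b])
        if (tot == 0)
            stop("Bray-Curtis undefined for all-zero sample pair (",
                 colnames(profiles)[a], ", ", colnames(profiles)[b], ")")
        d[a, b] <- d[b, a] <- sum(abs(profiles[, a] - profiles[, b])) / tot
    }
    stats::as.dist(d)
}

# Pool-adjacent-violators fit of distances against the dissimilarity rank
# order (primary approach to ties: within tied dissimilarities the current
# configuration distances are left free, sorted ascending before the fit).
.disparities <- function(dvec, delta) {
    o <- order(dvec, delta)
    fit <- stats::isoreg(delta[o])$yf
    dhat <- numeric(length(delta))
    dhat[o] <- fit
    dhat
}

.kruskalStress1 <- function(delta, dhat) {
    sqrt(sum((delta - dhat)^2) / sum(delta^2))
}

.nmdsOnce <- function(dvec, X, maxIter, tol) {
    n <- nrow(X)
    stress <- Inf
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        delta <- as.vector(stats::dist(X))
        dhat <- .disparities(dvec, delta)
        s <- .kruskalStress1(delta, dhat)
        if (is.finite(stress) && abs(stress - s) < tol) {
            stress <- min(stress, s)
            converged <- TRUE
            break
        }
        stress <- s
        # Guttman transform towards the disparities
        ratio <- ifelse(delta > 0, dhat / delta, 0)
        B <- matrix(0, n, n)
        B[lower.tri(B)] <- -ratio
        B <- B + t(B)
        diag(B) <- -rowSums(B)
        X <- B %*% X / n
    }
    X <- sweep(X, 2L, colMeans(X))
    list(X = X, stress = stress, converged = converged)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal-style NMDS: configuration distances are fit to the
#' dissimilarity rank order by monotone (isotonic) regression with
#' primary tie handling, and the configuration is updated by the Guttman
#' majorization transform until the stress-1 change falls below
#' \code{tol}. The first start is the classical (metric) MDS solution
#' from \code{stats::cmdscale}; the remaining \code{nRestarts - 1} starts
#' are random, and the lowest-stress configuration wins. Stress-1
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}} at or above 0.20 marks the
#' ordination as unreliable (\code{show} flags it).
#'
#' @param d a \code{dist} or symmetric dissimilarity matrix, n >= 4.
#' @param k embedding dimension (default 2).
#' @param nRestarts number of starts including the metric one
#'   (default 20).
#' @param maxIter iteration cap per start (default 500).
#' @param tol stress-change convergence tolerance (default 1e-6).
#' @param seed integer seed for the random starts (required).
#' @return an [NmdsResult-class]; coordinates are centred at the origin.
#' @export
nmds <- function(d, k = 2L, nRestarts = 20L, maxIter = 500L, tol = 1e-6,
                 seed) {
    if (missing(seed))
        stop("nmds requires an explicit seed")
    d <- stats::as.dist(d)
    n <- attr(d, "Size")
    if (n < 4L)
        stop("need >= 4 samples for NMDS")
    dvec <- as.vector(d)
    if (any(is.na(dvec)) || any(dvec < 0))
        stop("dissimilarities must be non-negative and complete")
    set.seed(seed)
    best <- NULL
    for (r in seq_len(nRestarts)) {
        X0 <- if (r == 1L) {
            cm <- stats::cmdscale(d, k = k)
            if (ncol(cm) < k)
                cm <- cbind(cm, matrix(stats::rnorm(n * (k - ncol(cm)),
                                                    sd = 1e-4), n))
            cm
        } else {
            matrix(stats::rnorm(n * k), n, k)
        }
        fit <- .nmdsOnce(dvec, X0, maxIter, tol)
        if (is.null(best) || fit$stress < best$stress)
            best <- fit
    }
    coords <- best$X
    rownames(coords) <- attr(d, "Labels")
    if (best$stress >= 0.20)
        warning(sprintf(
            "stress %.3f >= 0.20: ordination should not be interpreted",
            best$stress))
    methods::new("NmdsResult", coordinates = coords,
                 stress = best$stress, converged = best$converged,
                 nRestarts = as.integer(nRestarts),
                 seed = as.integer(seed))
}

.groupIndexList <- function(groups) {
    groups <- factor(groups)
    if (nlevels(groups) < 2L)
        stop("need >= 2 groups")
    split(seq_along(groups), groups)
}

# Sums of squares from a squared-distance matrix for one grouping
# (Anderson's pseudo-F; equivalently obtained from the Gower-centred
# matrix, but the direct distance form permutes faster).
.permanovaSS <- function(D2, idx) {
    n <- nrow(D2)
    ss_total <- sum(D2) / (2 * n)
    ss_within <- sum(vapply(idx, function(g)
        sum(D2[g, g]) / (2 * length(g)), numeric(1L)))
    c(total = ss_total, within = ss_within)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor partitioning of the variation in a dissimilarity matrix
#' among the levels of \code{groups}. With \eqn{SS_T = \sum_{i<j}
#' d_{ij}^2 / n} and \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g},
#' the pseudo-F is \eqn{(SS_A / (a - 1)) / (SS_W / (n - a))} with
#' \eqn{SS_A = SS_T - SS_W}, and the effect size is \eqn{R^2 = SS_A /
#' SS_T}. Significance is assessed by permuting the sample labels:
#' \eqn{p = (1 + \#\{F_\pi \ge F\}) / (1 + n_\mathrm{perm})}, so p is
#' floored at \eqn{1 / (n_\mathrm{perm} + 1)}. Given a seed, the p-value
#' is bit-reproducible.
#'
#' @param d \code{dist} or symmetric dissimilarity matrix.
#' @param groups factor of group labels (>= 2 levels; single-sample
#'   groups draw a warning).
#' @param nPermutations number of label permutations (default 999).
#' @param seed integer seed (required).
#' @return a [PermutationTestResult-class] with \code{effect} = R-squared
#'   and \code{statistic} = pseudo-F.
#' @export
permanova <- function(d, groups, nPermutations = 999L, seed) {
    if (missing(seed))
        stop("permanova requires an explicit seed")
    D <- as.matrix(stats::as.dist(d))
    groups <- factor(groups)
    if (length(groups) != nrow(D))
        stop("groups length must match the distance matrix")
    idx <- .groupIndexList(groups)
    if (any(lengths(idx) < 2L))
        warning("group(s) with a single sample: ",
                paste(names(idx)[lengths(idx) < 2L], collapse = ", "))
    n <- nrow(D)
    a <- length(idx)
    D2 <- D^2
    ss <- .permanovaSS(D2, idx)
    ss_among <- ss[["total"]] - ss[["within"]]
    if (ss[["within"]] <= 0)
        warning("within-group sum of squares is zero; F is singular")
    f_obs <- (ss_among / (a - 1)) / (ss[["within"]] / (n - a))
    r2 <- ss_among / ss[["total"]]
    set.seed(seed)
    sizes <- lengths(idx)
    hits <- 0L
    for (b in seq_len(nPermutations)) {
        perm <- sample.int(n)
        pidx <- split(perm, rep.int(seq_along(sizes), sizes))
        ssp <- .permanovaSS(D2, pidx)
        fp <- ((ssp[["total"]] - ssp[["within"]]) / (a - 1)) /
            (ssp[["within"]] / (n - a))
        if (fp >= f_obs)
            hits <- hits + 1L
    }
    methods::new("PermutationTestResult", method = "PERMANOVA",
        effect = unname(r2), statistic = unname(f_obs),
        p = (1 + hits) / (1 + nPermutations),
        nPermutations = as.integer(nPermutations),
        seed = as.integer(seed))
}

.anosimR <- function(rk, within) {
    M <- length(rk)
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

#' ANOSIM: analysis of similarities
#'
#' Rank-based contrast of between- versus within-group dissimilarities:
#' all \eqn{M = n(n-1)/2} dissimilarities are ranked (ties get average
#' ranks) and \deqn{R = (\bar r_B - \bar r_W) / (M / 2)} lies in
#' [-1, 1], 0 under the null and 1 for perfectly separated groups — the
#' statistic conventionally reported as a "global R". The permutation
#' p-value is computed exactly as in [permanova()].
#'
#' @inheritParams permanova
#' @return a [PermutationTestResult-class] with \code{effect} =
#'   \code{statistic} = R.
#' @export
anosim <- function(d, groups, nPermutations = 999L, seed) {
    if (missing(seed))
        stop("anosim requires an explicit seed")
    D <- as.matrix(stats::as.dist(d))
    groups <- factor(groups)
    n <- nrow(D)
    if (length(groups) != n)
        stop("groups length must match the distance matrix")
    if (nlevels(groups) < 2L)
        stop("need >= 2 groups")
    pairs <- which(lower.tri(D), arr.ind = TRUE)
    rk <- rank(D[lower.tri(D)])
    g <- as.integer(groups)
    within_obs <- g[pairs[, 1L]] == g[pairs[, 2L]]
    r_obs <- .anosimR(rk, within_obs)
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(nPermutations)) {
        gp <- g[sample.int(n)]
        within <- gp[pairs[, 1L]] == gp[pairs[, 2L]]
        if (.anosimR(rk, within) >= r_obs)
            hits <- hits + 1L
    }
    methods::new("PermutationTestResult", method = "ANOSIM",
        effect = r_obs, statistic = r_obs,
        p = (1 + hits) / (1 + nPermutations),
        nPermutations = as.integer(nPermutations),
        seed = as.integer(seed))
}
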