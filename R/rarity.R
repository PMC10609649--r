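#' Classify OTUs as abundant, rare, or intermediate
#'
#' Rule-based rarity classification on per-sample relative abundances,
#' judged over all samples:
#' \itemize{
#'   \item \strong{abundant}: reaches \code{upper} (default 1\%) in at
#'     least one sample and is never rare (never below \code{lower},
#'     default 0.01\%) in any sample;
#'   \item \strong{rare}: falls below \code{lower} in at least one sample
#'     and never reaches \code{upper};
#'   \item \strong{intermediate}: everything satisfying neither rule, so
#'     the three labels partition the OTU set.
#' }
#' An OTU absent (0 reads) from any sample counts as below \code{lower}
#' there, so it can never be abundant.
#'
#' @param x count matrix or [OtuExperiment-class].
#' @param upper abundance threshold for "abundant" (fraction, default
#'   0.01).
#' @param lower threshold below which an OTU is rare in a sample
#'   (fraction, default 1e-4).
#' @return DataFrame with \code{otu_id}, \code{label} (factor abundant /
#'   rare / intermediate), \code{max_rel_abund}, \code{min_rel_abund}.
#' @examples
#' cts <- matrix(c(900L, 100L, 980L, 20L), 2, 2,
#'     dimnames = list(c("big", "small"), c("s1", "s2")))
#' classifyRarity(cts)
#' @export
classifyRarity <- function(x, upper = 0.01, lower = 1e-4) {
    if (upper <= lower)
        stop("config error: upper must exceed lower")
    if (lower <= 0)
        stop("config error: lower must be > 0")
    rel <- relativeAbundance(x)
    mx <- apply(rel, 1L, max)
    mn <- apply(rel, 1L, min)
    label <- ifelse(mx >= upper & mn >= lower, "abundant",
             ifelse(mn < lower & mx < upper, "rare", "intermediate"))
    S4Vectors::DataFrame(
        otu_id = rownames(rel),
        label = factor(label, levels = c("abundant", "rare",
                                         "intermediate")),
        max_rel_abund = unname(mx),
        min_rel_abund = unname(mn),
        row.names = rownames(rel))
}

#' Detect period-sensitive OTUs by fold change
#'
#' Within each stratum (by default size fraction x treatment), computes
#' each OTU's mean relative abundance per cultivation period and flags the
#' OTU when the largest pairwise ratio of period means exceeds
#' \code{fold} (default 10; the max-ratio formulation covers both the
#' "more than 10 times" and "less than 0.1 times" directions). A
#' pseudo-abundance \code{epsilon} is added to numerator and denominator
#' so periods where the OTU vanishes -- its motivating case -- yield
#' finite ratios. An OTU is sensitive when it is flagged in at least one
#' stratum and is detected (> 0 reads) in at least two distinct periods.
#' Strata with fewer than two periods are skipped with a warning.
#'
#' @param x an [OtuExperiment-class] whose colData has a \code{period}
#'   column and the \code{stratifyBy} columns.
#' @param fold ratio threshold (> 1), default 10.
#' @param epsilon pseudo-abundance guarding zero means (default 1e-6).
#' @param stratifyBy colData columns defining strata (default fraction
#'   and treatment; use \code{character(0)} to pool all samples).
#' @return DataFrame with one row per OTU x stratum: \code{otu_id},
#'   \code{stratum}, \code{max_ratio}, \code{flagged} (this stratum),
#'   \code{is_sensitive} (OTU-level verdict, identical across an OTU's
#'   rows), plus a \code{period_means} matrix column. The vector of
#'   sensitive OTU ids is available via [sensitiveOtus()].
#' @export
detectSensitiveOtus <- function(x, fold = 10, epsilon = 1e-6,
                                stratifyBy = c("fraction", "treatment")) {
    if (fold <= 1)
        stop("fold must be > 1")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (!"period" %in% colnames(cd))
        stop("colData must contain a 'period' column")
    missing_cols <- setdiff(stratifyBy, colnames(cd))
    if (length(missing_cols))
        stop("stratifyBy column(s) not in colData: ",
             paste(missing_cols, collapse = ", "))
    rel <- relativeAbundance(x)
    strata <- if (length(stratifyBy) == 0L)
        rep("all", ncol(rel))
    else
        do.call(paste, c(cd[stratifyBy], sep = "."))
    all_periods <- sort(unique(cd$period))
    res <- list()
    for (st in unique(strata)) {
        in_st <- strata == st
        pers <- sort(unique(cd$period[in_st]))
        if (length(pers) < 2L) {
            warning("stratum '", st, "' has a single period; skipped")
            next
        }
        means <- matrix(NA_real_, nrow(rel), length(all_periods),
                        dimnames = list(NULL, as.character(all_periods)))
        for (p in pers)
            means[, as.character(p)] <- rowMeans(
                rel[, in_st & cd$period == p, drop = FALSE])
        shifted <- means[, as.character(pers), drop = FALSE] + epsilon
        max_ratio <- apply(shifted, 1L, max) / apply(shifted, 1L, min)
        res[[st]] <- S4Vectors::DataFrame(
            otu_id = rownames(rel),
            stratum = st,
            max_ratio = unname(max_ratio),
            flagged = unname(max_ratio > fold),
            period_means = I(unname(means)))
    }
    if (length(res) == 0L)
        stop("no stratum with >= 2 periods")
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    # detected (>0 reads) in >= 2 distinct periods, across all samples
    cts <- otuCounts(x)
    n_periods_detected <- vapply(rownames(cts), function(o)
        length(unique(cd$period[cts[o, ] > 0])), integer(1L))
    flagged_any <- tapply(out$flagged, out$otu_id, any)
    sens <- flagged_any[rownames(cts)] & n_periods_detected >= 2L
    out$is_sensitive <- unname(sens[out$otu_id])
    S4Vectors::metadata(out) <- list(fold = fold, epsilon = epsilon,
                                     periods = all_periods)
    out
}

#' Sensitive OTU identifiers
#'
#' @param records output of [detectSensitiveOtus()].
#' @return character vector of OTU ids judged sensitive.
#' @export
sensitiveOtus <- function(records) {
    unique(records$otu_id[records$is_sensitive])
}

#' Heatmap matrix of sensitive-OTU relative abundances
#'
#' Builds the matrix behind the usual sensitive-OTU heatmap: rows are
#' sensitive OTUs, columns are samples ordered by fraction, then
#' treatment, then period, and entries are log10(relative abundance +
#' epsilon) ("lg" transformed). Row annotations from [classifyRarity()]
#' (abundant / rare / intermediate) are attached as the
#' \code{"rarity"} attribute.
#'
#' @param records output of [detectSensitiveOtus()].
#' @param x the [OtuExperiment-class] the records came from.
#' @param epsilon floor added before the log (default 1e-6, so a zero
#'   abundance maps to -6).
#' @param rarity optional precomputed [classifyRarity()] result.
#' @return numeric matrix; attribute \code{"rarity"} holds the row
#'   labels.
#' @export
sensitiveHeatmapMatrix <- function(records, x, epsilon = 1e-6,
                                   rarity = classifyRarity(x)) {
    ids <- sensitiveOtus(records)
    if (length(ids) == 0L)
        stop("no sensitive OTUs in records")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    ord <- order(cd$fraction,
                 if ("treatment" %in% colnames(cd)) cd$treatment else
                     rep(1L, nrow(cd)),
                 if ("period" %in% colnames(cd)) cd$period else
                     rep(1L, nrow(cd)))
    rel <- relativeAbundance(x)[ids, ord, drop = FALSE]
    m <- log10(rel + epsilon)
    attr(m, "rarity") <- as.character(rarity[ids, "label"])
    m
}

#' Plot the sensitive-OTU heatmap
#'
#' Thin wrapper around \pkg{pheatmap} for the matrix from
#' [sensitiveHeatmapMatrix()], with rows annotated by rarity class and
#' columns kept in fraction / treatment / period order.
#'
#' @param m matrix from [sensitiveHeatmapMatrix()].
#' @param ... passed to \code{pheatmap::pheatmap}.
#' @return the pheatmap object, invisibly.
#' @export
plotSensitiveHeatmap <- function(m, ...) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
        stop("plotSensitiveHeatmap needs the 'pheatmap' package")
    ann <- data.frame(rarity = attr(m, "rarity"), row.names = rownames(m))
    ph <- pheatmap::pheatmap(m, cluster_cols = FALSE,
                             annotation_row = ann, ...)
    invisible(ph)
}
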