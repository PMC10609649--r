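#' Particle-association niche (PAN) index per OTU
#'
#' Positions each OTU on a continuous niche axis from a completely
#' free-living (0) to a completely particle-attached (1) lifestyle. With
#' FL samples scored 0 and PA samples scored 1, the index is the
#' abundance-weighted mean of the sample scores:
#' \deqn{\mathrm{PAN}_i = \frac{\sum_s w_{is}\, [\mathrm{fraction}_s =
#' \mathrm{PA}]}{\sum_s w_{is}}}
#' where \eqn{w_{is}} is OTU i's abundance in sample s. An OTU occurring
#' only in PA samples scores 1, only in FL samples 0, and one equally
#' distributed across FL and PA samples 0.5.
#'
#' By default the weights are per-sample \emph{relative} abundances, so a
#' deeply sequenced sample cannot dominate the mean; \code{weight =
#' "raw"} uses read counts directly. Only OTUs with more than
#' \code{minSequences} total reads (default 10) are scored.
#'
#' @param x an [OtuExperiment-class] (every sample carries an FL/PA
#'   fraction label).
#' @param minSequences OTUs with total reads at or below this are omitted
#'   (default 10).
#' @param weight \code{"relative"} (default) or \code{"raw"}.
#' @return DataFrame with \code{otu_id}, \code{pan} in [0, 1],
#'   \code{total_sequences}, \code{n_samples_present}.
#' @examples
#' cts <- matrix(c(0L, 12L, 0L, 8L, 10L, 0L, 10L, 0L), 2, 4,
#'     dimnames = list(c("flOtu", "paOtu"),
#'                     c("pa1", "pa2", "fl1", "fl2")))
#' md <- data.frame(sample_id = colnames(cts),
#'                  fraction = c("PA", "PA", "FL", "FL"))
#' panIndex(OtuExperiment(cts, md))
#' @export
panIndex <- function(x, minSequences = 10, weight = c("relative", "raw")) {
    weight <- match.arg(weight)
    if (minSequences < 0)
        stop("minSequences must be >= 0")
    fr <- sampleFractions(x)
    if (any(is.na(fr)))
        stop("every sample needs an FL or PA fraction label")
    if (!any(fr == "PA") || !any(fr == "FL"))
        warning("only one fraction present; PAN degenerates to 0 or 1")
    cts <- otuCounts(x)
    total <- rowSums(cts)
    keep <- total > minSequences
    w <- if (weight == "relative") relativeAbundance(x) else cts
    w <- w[keep, , drop = FALSE]
    pan <- rowSums(w[, fr == "PA", drop = FALSE]) / rowSums(w)
    S4Vectors::DataFrame(
        otu_id = rownames(w),
        pan = unname(pan),
        total_sequences = unname(total[keep]),
        n_samples_present = unname(rowSums(cts[keep, , drop = FALSE] > 0)),
        row.names = rownames(w))
}

#' Taxon-level PAN summaries
#'
#' Aggregates per-OTU PAN indices to a taxonomic rank, stratified by
#' rarity class and optionally by sample groups (e.g. treatment), the
#' layout of the classic per-treatment dot plot with its 0.5 reference
#' line. When \code{groupBy} is given, the PAN index is recomputed within
#' each group of samples, so each panel reflects only its own samples.
#' The summary per taxon x rarity x group is the mean and standard error
#' (\eqn{s/\sqrt{n}}; 0 for singletons) of the member OTUs' PAN values.
#'
#' @param x an [OtuExperiment-class] with taxonomy in rowData.
#' @param rarity output of [classifyRarity()] (computed if omitted).
#' @param rank taxonomy rank to aggregate on (default \code{"class"}).
#' @param groupBy optional colData columns splitting samples into groups.
#' @param minSequences,weight passed to [panIndex()].
#' @return DataFrame with \code{taxon}, \code{rarity}, \code{group},
#'   \code{mean_pan}, \code{se_pan}, \code{n_otus}.
#' @export
taxonPanSummary <- function(x, rarity = classifyRarity(x), rank = "class",
                            groupBy = NULL, minSequences = 10,
                            weight = c("relative", "raw")) {
    weight <- match.arg(weight)
    tax <- taxonomyTable(x)
    if (!rank %in% colnames(tax))
        stop("rank '", rank, "' not in taxonomy")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    groups <- if (is.null(groupBy)) rep("all", ncol(x)) else
        do.call(paste, c(cd[groupBy], sep = "."))
    out <- list()
    for (g in unique(groups)) {
        xg <- x[, groups == g]
        if (!all(c("FL", "PA") %in% as.character(xg$fraction)))
            next
        pans <- panIndex(xg, minSequences = minSequences, weight = weight)
        taxon <- as.character(tax[pans$otu_id, rank])
        rar <- as.character(rarity[pans$otu_id, "label"])
        key <- interaction(taxon, rar, drop = TRUE, sep = "\r")
        agg <- tapply(pans$pan, key, function(v)
            c(mean = mean(v),
              se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0,
              n = length(v)))
        parts <- strsplit(names(agg), "\r", fixed = TRUE)
        out[[g]] <- S4Vectors::DataFrame(
            taxon = vapply(parts, `[`, character(1L), 1L),
            rarity = vapply(parts, `[`, character(1L), 2L),
            group = g,
            mean_pan = unname(vapply(agg, `[[`, numeric(1L), "mean")),
            se_pan = unname(vapply(agg, `[[`, numeric(1L), "se")),
            n_otus = unname(as.integer(vapply(agg, `[[`, numeric(1L),
                                              "n"))))
    }
    if (length(out) == 0L)
        stop("no group contains both FL and PA samples")
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Lifestyle-shift trajectories of taxon-level PAN
#'
#' Tracks the mean PAN of each taxon across cultivation periods: the PAN
#' index is recomputed within each period's samples, averaged per taxon,
#' and the per-taxon least-squares slope against time classifies the
#' taxon as shifting \code{"toward PA"} (positive slope),
#' \code{"toward FL"} (negative), or \code{"stable"} (zero). A taxon-wide
#' mean PAN below 0.5 indicates an overall preference for the free-living
#' lifestyle.
#'
#' @param x an [OtuExperiment-class] with \code{period} in colData.
#' @param rank taxonomy rank (default \code{"class"}).
#' @param minSequences,weight passed to [panIndex()].
#' @return DataFrame with one row per taxon x period: \code{taxon},
#'   \code{period}, \code{mean_pan}, \code{n_otus},
#'   \code{delta_from_first}, plus per-taxon \code{slope} (PAN per hour)
#'   and \code{direction} repeated across the taxon's rows.
#' @export
lifestyleShift <- function(x, rank = "class", minSequences = 10,
                           weight = c("relative", "raw")) {
    weight <- match.arg(weight)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (!"period" %in% colnames(cd))
        stop("colData must contain a 'period' column")
    periods <- sort(unique(cd$period))
    usable <- periods[vapply(periods, function(p)
        all(c("FL", "PA") %in% as.character(cd$fraction[cd$period == p])),
        logical(1L))]
    if (length(usable) < 2L)
        stop("need >= 2 periods containing both fractions")
    tax <- taxonomyTable(x)
    rows <- list()
    for (p in usable) {
        xp <- x[, cd$period == p]
        pans <- panIndex(xp, minSequences = minSequences, weight = weight)
        taxon <- as.character(tax[pans$otu_id, rank])
        mean_pan <- tapply(pans$pan, taxon, mean)
        rows[[as.character(p)]] <- data.frame(
            taxon = names(mean_pan), period = p,
            mean_pan = unname(mean_pan),
            n_otus = unname(as.integer(table(taxon)[names(mean_pan)])))
    }
    df <- do.call(rbind, rows)
    first <- df[df$period == usable[1L], c("taxon", "mean_pan")]
    df$delta_from_first <- df$mean_pan -
        first$mean_pan[match(df$taxon, first$taxon)]
    slope <- vapply(split(df, df$taxon), function(d) {
        if (nrow(d) < 2L || any(is.na(d$mean_pan))) return(NA_real_)
        unname(stats::coef(stats::lm(mean_pan ~ period, data = d))[2L])
    }, numeric(1L))
    df$slope <- slope[df$taxon]
    df$direction <- ifelse(is.na(df$slope), NA_character_,
                    ifelse(df$slope > 0, "toward PA",
                    ifelse(df$slope < 0, "toward FL", "stable")))
    res <- S4Vectors::DataFrame(df[order(df$taxon, df$period), ])
    rownames(res) <- NULL
    res
}
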