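#' Construct an OtuExperiment
#'
#' Bundles an OTU count matrix (OTU rows x sample columns), the per-sample
#' design metadata, and an optional taxonomy table into a validated
#' [OtuExperiment-class] object. The metadata join is strict: every sample
#' column must have exactly one metadata row and vice versa, unless
#' \code{subset = TRUE}, in which case the table is restricted to the
#' samples present in both (an opt-in, never silent, subset mode).
#'
#' @param counts integer matrix of read counts, OTUs in rows, samples in
#'   columns, both with unique dimnames.
#' @param sampleData data.frame or DataFrame of per-sample metadata with a
#'   \code{sample_id} column (or rownames) and at least a \code{fraction}
#'   column with values \code{"FL"} / \code{"PA"}. Typical further columns:
#'   \code{treatment}, \code{dose}, \code{period}, \code{replicate},
#'   \code{algal_cell_change}.
#' @param taxonomy optional data.frame/DataFrame keyed by \code{otu_id} (or
#'   rownames) with rank columns (phylum, class, order, family, genus).
#'   Missing ranks and OTUs without a row are filled with
#'   \code{"Unclassified"} so taxon aggregation is total. Every OTU named
#'   in the taxonomy must exist in \code{counts}.
#' @param subset if TRUE, keep only samples present in both \code{counts}
#'   and \code{sampleData}; if FALSE (default), any mismatch is an error.
#' @return An [OtuExperiment-class].
#' @examples
#' cts <- matrix(c(5L, 0L, 3L, 7L), 2, 2,
#'     dimnames = list(c("OTU1", "OTU2"), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"), fraction = c("FL", "PA"))
#' oe <- OtuExperiment(cts, md)
#' otuCounts(oe)
#' @export
OtuExperiment <- function(counts, sampleData, taxonomy = NULL,
                          subset = FALSE) {
    counts <- .asCountMatrix(counts)
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% colnames(sampleData)) {
        rownames(sampleData) <- as.character(sampleData$sample_id)
    }
    if (is.null(rownames(sampleData)))
        stop("sampleData needs a 'sample_id' column or rownames")
    if (subset) {
        keep <- intersect(colnames(counts), rownames(sampleData))
        if (length(keep) == 0L)
            stop("no samples shared between counts and sampleData")
        counts <- counts[, keep, drop = FALSE]
        sampleData <- sampleData[keep, , drop = FALSE]
    } else {
        missing_md <- setdiff(colnames(counts), rownames(sampleData))
        extra_md <- setdiff(rownames(sampleData), colnames(counts))
        if (length(missing_md) || length(extra_md))
            stop("sample metadata mismatch; missing: [",
                 paste(missing_md, collapse = ", "), "] extra: [",
                 paste(extra_md, collapse = ", "),
                 "] (use subset = TRUE to intersect)")
        sampleData <- sampleData[colnames(counts), , drop = FALSE]
    }
    rowdat <- .alignTaxonomy(taxonomy, rownames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(sampleData),
        rowData = rowdat)
    methods::new("OtuExperiment", se)
}

.asCountMatrix <- function(counts) {
    counts <- as.matrix(counts)
    if (!is.numeric(counts))
        stop("counts must be numeric")
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have OTU rownames and sample colnames")
    storage.mode(counts) <- "integer"
    counts
}

.taxRanks <- c("phylum", "class", "order", "family", "genus")

.alignTaxonomy <- function(taxonomy, otu_ids) {
    out <- S4Vectors::DataFrame(row.names = otu_ids)
    if (is.null(taxonomy)) {
        for (r in .taxRanks) out[[r]] <- rep("Unclassified", length(otu_ids))
        return(out)
    }
    taxonomy <- as.data.frame(taxonomy)
    if ("otu_id" %in% colnames(taxonomy))
        rownames(taxonomy) <- as.character(taxonomy$otu_id)
    unknown <- setdiff(rownames(taxonomy), otu_ids)
    if (length(unknown))
        stop("taxonomy rows for OTUs absent from the table: ",
             paste(utils::head(unknown, 5L), collapse = ", "))
    ranks <- intersect(.taxRanks, colnames(taxonomy))
    if (length(ranks) == 0L)
        stop("taxonomy has none of the rank columns: ",
             paste(.taxRanks, collapse = ", "))
    for (r in ranks) {
        v <- rep("Unclassified", length(otu_ids))
        idx <- match(rownames(taxonomy), otu_ids)
        val <- as.character(taxonomy[[r]])
        val[is.na(val) | val == ""] <- "Unclassified"
        v[idx] <- val
        out[[r]] <- v
    }
    for (r in setdiff(.taxRanks, ranks))
        out[[r]] <- rep("Unclassified", length(otu_ids))
    out
}

#' Accessors for OtuExperiment
#'
#' \code{otuCounts} returns the integer count matrix; \code{sampleFractions}
#' the FL/PA factor; \code{sampleDepths} the per-sample read depths;
#' \code{taxonomyTable} the rowData taxonomy as a DataFrame.
#'
#' @param x an [OtuExperiment-class].
#' @return See individual descriptions.
#' @name otuCounts
#' @aliases otuCounts sampleFractions sampleDepths taxonomyTable
#' @export
otuCounts <- function(x) {
    SummarizedExperiment::assay(x, "counts")
}

#' @rdname otuCounts
#' @export
sampleFractions <- function(x) {
    factor(as.character(x$fraction), levels = c("FL", "PA"))
}

#' @rdname otuCounts
#' @export
sampleDepths <- function(x) {
    colSums(otuCounts(x))
}

#' @rdname otuCounts
#' @export
taxonomyTable <- function(x) {
    SummarizedExperiment::rowData(x)[, intersect(
        .taxRanks, colnames(SummarizedExperiment::rowData(x))), drop = FALSE]
}

setMethod("show", "OtuExperiment", function(object) {
    cts <- otuCounts(object)
    cat("OtuExperiment:", nrow(cts), "OTUs x", ncol(cts), "samples\n")
    fr <- table(sampleFractions(object))
    cat("  fractions: FL =", fr[["FL"]], ", PA =", fr[["PA"]], "\n")
    cat("  read depth:", paste(range(colSums(cts)), collapse = "-"), "\n")
    cd <- setdiff(colnames(SummarizedExperiment::colData(object)),
                  "fraction")
    if (length(cd))
        cat("  colData:", paste(cd, collapse = ", "), "\n")
})

setMethod("show", "NmdsResult", function(object) {
    cat(sprintf("NMDS (k = %d): stress = %.4f (%s), %d restart(s)\n",
        ncol(object@coordinates), object@stress,
        if (object@stress < 0.20) "acceptable < 0.20"
        else "NOT acceptable >= 0.20",
        object@nRestarts))
})

setMethod("show", "PermutationTestResult", function(object) {
    lab <- if (object@method == "PERMANOVA") "R2" else "R"
    stat <- if (object@method == "PERMANOVA") "pseudo-F" else "R"
    cat(sprintf("%s: %s = %.4f, %s = %.4f, p = %.4g (%d permutations)\n",
        object@method, lab, object@effect, stat, object@statistic,
        object@p, object@nPermutations))
})
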