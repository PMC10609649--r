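#' Read an OTU count table from TSV
#'
#' Reads a tab-separated OTU table with OTU identifiers in the first
#' column and sample identifiers in the header row. Two dialects are
#' supported: plain TSV (\code{dialect = "tsv"}) and BIOM-style dense TSV
#' whose header line starts with \code{"#OTU ID"} (\code{dialect =
#' "biom"}); \code{"auto"} sniffs the first line. The table orientation is
#' fixed as OTU rows x sample columns; set \code{transpose = TRUE}
#' explicitly if your file is sample rows x OTU columns (silent
#' auto-transposition would hide data errors).
#'
#' Validation is strict: negative, non-numeric or non-integral cells,
#' duplicated identifiers, empty tables, and zero-depth samples are all
#' errors, never silently repaired or dropped.
#'
#' @param path path to the file.
#' @param dialect \code{"auto"}, \code{"tsv"} or \code{"biom"}.
#' @param transpose set TRUE when the file stores samples in rows.
#' @return integer matrix, OTUs in rows, samples in columns.
#' @export
readOtuTable <- function(path, dialect = c("auto", "tsv", "biom"),
                         transpose = FALSE) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("no such file: ", path)
    first <- readLines(path, n = 1L)
    if (dialect == "auto")
        dialect <- if (startsWith(first, "#OTU ID")) "biom" else "tsv"
    if (dialect == "biom" && !startsWith(first, "#OTU ID"))
        stop("format error: BIOM-style dense TSV must start with '#OTU ID'")
    df <- utils::read.table(path, header = TRUE, sep = "\t",
        comment.char = "", check.names = FALSE, quote = "",
        stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("format error: empty OTU table")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("format error: duplicate OTU ids")
    mat <- as.matrix(df[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(mat)))
        stop("format error: duplicate sample ids")
    if (!is.numeric(mat))
        stop("format error: non-numeric cells in OTU table")
    rownames(mat) <- ids
    if (transpose)
        mat <- t(mat)
    if (any(is.na(mat)))
        stop("format error: missing values in OTU table")
    if (any(mat < 0))
        stop("format error: negative counts")
    if (any(mat != round(mat)))
        stop("format error: non-integral counts")
    if (any(colSums(mat) <= 0))
        stop("zero read depth in sample(s): ",
             paste(colnames(mat)[colSums(mat) <= 0], collapse = ", "))
    storage.mode(mat) <- "integer"
    mat
}

#' Write an OTU count table as TSV
#'
#' Inverse of [readOtuTable()]; \code{readOtuTable(writeOtuTable(x, f))}
#' round-trips counts and identifiers exactly.
#'
#' @param x integer count matrix or [OtuExperiment-class].
#' @param path output path.
#' @param dialect \code{"tsv"} (first header cell \code{OTU_ID}) or
#'   \code{"biom"} (dense BIOM-style, first header cell \code{#OTU ID}).
#' @return \code{path}, invisibly.
#' @export
writeOtuTable <- function(x, path, dialect = c("tsv", "biom")) {
    dialect <- match.arg(dialect)
    if (methods::is(x, "OtuExperiment"))
        x <- otuCounts(x)
    lead <- if (dialect == "biom") "#OTU ID" else "OTU_ID"
    header <- paste(c(lead, colnames(x)), collapse = "\t")
    body <- vapply(seq_len(nrow(x)), function(i)
        paste(c(rownames(x)[i], x[i, ]), collapse = "\t"), character(1L))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read sample metadata / taxonomy TSV
#'
#' Plain tab-separated tables with a header row. \code{readSampleMetadata}
#' expects a \code{sample_id} column; \code{readTaxonomy} an \code{otu_id}
#' column plus any of the rank columns phylum, class, order, family,
#' genus (missing ranks become \code{"Unclassified"} when attached to an
#' [OtuExperiment-class]).
#'
#' @param path path to the TSV file.
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
        check.names = FALSE, quote = "", stringsAsFactors = FALSE,
        comment.char = "")
    if (!"sample_id" %in% colnames(df))
        stop("metadata must have a 'sample_id' column")
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in metadata")
    df
}

#' @rdname readSampleMetadata
#' @export
readTaxonomy <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
        check.names = FALSE, quote = "", stringsAsFactors = FALSE,
        comment.char = "")
    if (!"otu_id" %in% colnames(df))
        stop("taxonomy must have an 'otu_id' column")
    if (anyDuplicated(df$otu_id))
        stop("duplicate otu_id in taxonomy")
    df
}

#' Per-sample relative abundances
#'
#' Divides each sample (column) by its read depth, so every column sums
#' to one. The zero-depth case is an error naming the offending sample.
#'
#' @param x count matrix (OTU rows x sample columns) or
#'   [OtuExperiment-class].
#' @return numeric matrix of fractions in [0, 1]; columns sum to 1.
#' @examples
#' relativeAbundance(matrix(c(10, 30), 2, 1,
#'     dimnames = list(c("a", "b"), "s1")))
#' @export
relativeAbundance <- function(x) {
    if (methods::is(x, "OtuExperiment"))
        x <- otuCounts(x)
    depths <- colSums(x)
    if (any(depths <= 0))
        stop("zero read depth in sample(s): ",
             paste(colnames(x)[depths <= 0], collapse = ", "))
    sweep(x, 2L, depths, "/")
}

#' Hellinger transform
#'
#' Square root of per-sample relative abundances: entry
#' \eqn{\sqrt{n_{is} / N_s}}. Each column's squared entries sum to one, so
#' Euclidean distances on the transformed matrix are Hellinger distances;
#' the transform damps the dominance of abundant taxa and improves
#' normality of community data ahead of ordination and permutation tests.
#'
#' @inheritParams relativeAbundance
#' @return numeric matrix; columnwise sum of squares equals 1.
#' @export
hellingerTransform <- function(x) {
    sqrt(relativeAbundance(x))
}

#' Rarefy samples to a common depth
#'
#' Optional, off by default in all analyses: subsamples each sample
#' without replacement to \code{depth} reads. Samples shallower than
#' \code{depth} are an error (never silently dropped).
#'
#' @param x count matrix or [OtuExperiment-class].
#' @param depth target reads per sample; default the minimum sample depth.
#' @param seed integer seed for the subsampling.
#' @return integer matrix with all column sums equal to \code{depth}.
#' @export
rarefyCounts <- function(x, depth = min(colSums(m)), seed) {
    m <- if (methods::is(x, "OtuExperiment")) otuCounts(x) else x
    force(depth)
    if (missing(seed))
        stop("rarefyCounts requires an explicit seed")
    if (any(colSums(m) < depth))
        stop("sample(s) shallower than target depth: ",
             paste(colnames(m)[colSums(m) < depth], collapse = ", "))
    set.seed(seed)
    out <- m
    for (j in seq_len(ncol(m))) {
        reads <- rep.int(seq_len(nrow(m)), m[, j])
        keep <- sample(reads, depth)
        out[, j] <- tabulate(keep, nbins = nrow(m))
    }
    storage.mode(out) <- "integer"
    out
}
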