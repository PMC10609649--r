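#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' OtuExperiment: a size-fractionated OTU count container
#'
#' \code{OtuExperiment} extends
#' \linkS4class{SummarizedExperiment}: rows are OTUs, columns
#' are samples, and the single source of abundance truth is the
#' \code{"counts"} assay of non-negative integer read counts. Per-sample
#' design factors (size fraction, surfactin treatment, cultivation period,
#' replicate, algal-cell change) live in \code{colData}; taxonomic labels
#' (phylum ... genus) live in \code{rowData}.
#'
#' Validity requires a \code{"counts"} assay of non-negative, integral
#' values, unique OTU and sample identifiers, a positive read depth for
#' every sample, and a \code{fraction} column in \code{colData} restricted
#' to the levels \code{"FL"} (free-living, 0.22--5 um filter fraction) and
#' \code{"PA"} (particle-attached, > 5 um).
#'
#' @seealso [OtuExperiment()] the constructor; [otuCounts()],
#'   [sampleFractions()] accessors.
#' @name OtuExperiment-class
#' @aliases OtuExperiment-class
#' @exportClass OtuExperiment
setClass("OtuExperiment", contains = "SummarizedExperiment")

.validOtuExperiment <- function(object) {
    msg <- NULL
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cts)))
        msg <- c(msg, "counts contain NA")
    else {
        if (any(cts < 0))
            msg <- c(msg, "counts must be non-negative")
        if (any(cts != round(cts)))
            msg <- c(msg, "counts must be integral read counts")
        if (ncol(cts) > 0 && any(colSums(cts) <= 0))
            msg <- c(msg, sprintf("zero read depth in sample(s): %s",
                paste(colnames(cts)[colSums(cts) <= 0], collapse = ", ")))
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "OTU ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (!("fraction" %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData must contain a 'fraction' column (FL/PA)")
    else {
        fr <- as.character(object$fraction)
        if (!all(fr %in% c("FL", "PA")))
            msg <- c(msg, "fraction must be 'FL' or 'PA'")
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("OtuExperiment", .validOtuExperiment)

#' Simulation configuration for the synthetic community generator
#'
#' Holds every knob of the Dirichlet-multinomial size-fractionated
#' community generator. Construct with [simulationConfig()], which
#' documents the defaults and their rationale.
#'
#' @slot nOtus number of OTUs.
#' @slot treatments named numeric vector of surfactin doses (mg/L); names
#'   are treatment labels, the dose drives the lifestyle shift.
#' @slot periods list (one per treatment) of cultivation periods in hours.
#' @slot nReplicates replicate pairs per treatment x period cell.
#' @slot depthRange integer min/max reads per sample.
#' @slot baseAbundanceSigma log-normal shape of baseline abundances.
#' @slot panShiftSlope logit shift of particle allocation per (mg/L x day).
#' @slot beta0Mean,beta0Sd distribution of per-OTU baseline allocation
#'   logits.
#' @slot overdispersion Dirichlet concentration scaler (larger = closer to
#'   multinomial).
#' @slot classWeights named numeric vector of taxonomy class weights.
#' @slot seed integer seed; fixed seed gives bit-identical tables.
#' @name SimulationConfig-class
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
    nOtus = "integer",
    treatments = "numeric",
    periods = "list",
    nReplicates = "integer",
    depthRange = "integer",
    baseAbundanceSigma = "numeric",
    panShiftSlope = "numeric",
    beta0Mean = "numeric",
    beta0Sd = "numeric",
    overdispersion = "numeric",
    classWeights = "numeric",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (object@nOtus < 2L)
        msg <- c(msg, "nOtus must be >= 2")
    if (length(object@depthRange) != 2L || any(object@depthRange < 1L) ||
        object@depthRange[1L] > object@depthRange[2L])
        msg <- c(msg, "depthRange must be positive integers min <= max")
    if (object@overdispersion <= 0)
        msg <- c(msg, "overdispersion must be > 0")
    if (is.null(names(object@treatments)) ||
        anyDuplicated(names(object@treatments)))
        msg <- c(msg, "treatments must be uniquely named doses")
    if (length(object@periods) != length(object@treatments))
        msg <- c(msg, "periods must list one period set per treatment")
    if (object@nReplicates < 1L)
        msg <- c(msg, "nReplicates must be >= 1")
    if (any(object@classWeights < 0) || sum(object@classWeights) <= 0)
        msg <- c(msg, "classWeights must be non-negative, not all zero")
    if (is.null(msg)) TRUE else msg
})

#' Non-metric multidimensional scaling result
#'
#' Returned by [nmds()]. Coordinates are centred at the origin; stress is
#' Kruskal stress-1. Ordinations with stress at or above 0.20 are flagged
#' (\code{acceptable(object)} is \code{FALSE}) following the usual
#' interpretability criterion.
#'
#' @slot coordinates n x k matrix of sample coordinates.
#' @slot stress Kruskal stress-1 of the best restart.
#' @slot converged whether the best restart met the stress tolerance.
#' @slot nRestarts number of random restarts used.
#' @slot seed integer seed used.
#' @name NmdsResult-class
#' @aliases NmdsResult-class
#' @exportClass NmdsResult
setClass("NmdsResult", representation(
    coordinates = "matrix",
    stress = "numeric",
    converged = "logical",
    nRestarts = "integer",
    seed = "integer"
))

setValidity("NmdsResult", function(object) {
    if (object@stress < 0) "stress must be >= 0" else TRUE
})

#' Permutation test result for community composition
#'
#' Returned by [permanova()] and [anosim()]. \code{effect} is the
#' PERMANOVA R-squared (share of the total sum of squared dissimilarities
#' among groups) or the ANOSIM R (rank-based between- minus within-group
#' contrast in [-1, 1]); \code{statistic} is the pseudo-F or R; \code{p}
#' is the permutation p-value with floor 1 / (nPermutations + 1).
#'
#' @slot method "PERMANOVA" or "ANOSIM".
#' @slot effect R-squared (PERMANOVA) or R (ANOSIM).
#' @slot statistic pseudo-F (PERMANOVA) or R (ANOSIM).
#' @slot p permutation p-value.
#' @slot nPermutations number of label permutations.
#' @slot seed integer seed used for the permutations.
#' @name PermutationTestResult-class
#' @aliases PermutationTestResult-class
#' @exportClass PermutationTestResult
setClass("PermutationTestResult", representation(
    method = "character",
    effect = "numeric",
    statistic = "numeric",
    p = "numeric",
    nPermutations = "integer",
    seed = "integer"
))

setValidity("PermutationTestResult", function(object) {
    msg <- NULL
    if (!object@method %in% c("PERMANOVA", "ANOSIM"))
        msg <- c(msg, "method must be PERMANOVA or ANOSIM")
    if (object@p <= 0 || object@p > 1)
        msg <- c(msg, "p must be in (0, 1]")
    if (object@method == "PERMANOVA" &&
        (object@effect < 0 || object@effect > 1))
        msg <- c(msg, "PERMANOVA R-squared must be in [0, 1]")
    if (object@method == "ANOSIM" &&
        (object@effect < -1 || object@effect > 1))
        msg <- c(msg, "ANOSIM R must be in [-1, 1]")
    if (is.null(msg)) TRUE else msg
})
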