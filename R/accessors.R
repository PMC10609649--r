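#' Result accessors
#'
#' Accessor functions for [NmdsResult-class] and
#' [PermutationTestResult-class] objects: ordination coordinates and
#' stress, permutation effect size, test statistic, and p-value.
#'
#' @param object a result object.
#' @return \code{nmdsScores}: coordinate matrix; \code{nmdsStress}:
#'   Kruskal stress-1; \code{effectSize}: R-squared or ANOSIM R;
#'   \code{testStatistic}: pseudo-F or R; \code{pValue}: permutation
#'   p-value.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
nmdsScores <- function(object) object@coordinates

#' @rdname result-accessors
#' @export
nmdsStress <- function(object) object@stress

#' @rdname result-accessors
#' @export
effectSize <- function(object) object@effect

#' @rdname result-accessors
#' @export
testStatistic <- function(object) object@statistic

#' @rdname result-accessors
#' @export
pValue <- function(object) object@p
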