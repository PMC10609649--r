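#' Alpha diversity indices per sample
#'
#' Computes, from raw counts, the classic per-sample indices:
#' \itemize{
#'   \item OTU richness \eqn{S}: number of OTUs with > 0 reads;
#'   \item Shannon-Wiener \eqn{H = -\sum_i p_i \log p_i} (natural log by
#'     default; \code{logBase = "2"} matches older QIIME conventions);
#'   \item Simpson dominance \eqn{D = \sum_i p_i^2} and its diversity
#'     complement \eqn{1 - D} (dominance is the default headline value:
#'     small D alongside moderate H is the usual reporting convention);
#'   \item Pielou evenness \eqn{J = H / \log S}, undefined (NA) when
#'     \eqn{S = 1};
#'   \item Chao1 richness, bias-corrected by default:
#'     \eqn{S + F_1 (F_1 - 1) / (2 (F_2 + 1))} with \eqn{F_1, F_2} the
#'     singleton and doubleton counts (finite even when \eqn{F_2 = 0});
#'     the classic \eqn{S + F_1^2 / (2 F_2)} is available via
#'     \code{chao1 = "classic"}.
#' }
#'
#' @param x count matrix or [OtuExperiment-class].
#' @param logBase \code{"e"} (default) or \code{"2"} for Shannon and
#'   evenness.
#' @param chao1 \code{"bias-corrected"} (default) or \code{"classic"}.
#' @return DataFrame with \code{sample_id}, \code{richness},
#'   \code{shannon}, \code{simpson} (dominance D),
#'   \code{simpson_diversity} (1 - D), \code{evenness}, \code{chao1}.
#' @examples
#' cts <- matrix(rep(5L, 8), 8, 1, dimnames = list(paste0("o", 1:8), "u"))
#' alphaDiversity(cts)  # H = log 8, evenness 1, D = 1/8
#' @export
alphaDiversity <- function(x, logBase = c("e", "2"),
                           chao1 = c("bias-corrected", "classic")) {
    logBase <- match.arg(logBase)
    chao1 <- match.arg(chao1)
    if (methods::is(x, "OtuExperiment"))
        x <- otuCounts(x)
    lg <- if (logBase == "2") function(v) log2(v) else function(v) log(v)
    res <- lapply(seq_len(ncol(x)), function(j) {
        n <- x[, j]
        if (sum(n) <= 0)
            stop("zero read depth in sample: ", colnames(x)[j])
        p <- n[n > 0] / sum(n)
        S <- length(p)
        H <- -sum(p * lg(p))
        D <- sum(p^2)
        F1 <- sum(n == 1)
        F2 <- sum(n == 2)
        c1 <- if (chao1 == "bias-corrected")
            S + F1 * (F1 - 1) / (2 * (F2 + 1))
        else if (F1 == 0)
            S
        else
            S + F1^2 / (2 * F2)   # classic; infinite when F2 = 0, F1 > 0
        data.frame(richness = S, shannon = H, simpson = D,
                   simpson_diversity = 1 - D,
                   evenness = if (S > 1) H / lg(S) else NA_real_,
                   chao1 = c1)
    })
    res <- do.call(rbind, res)
    S4Vectors::DataFrame(sample_id = colnames(x), res,
                         row.names = colnames(x))
}

#' One-way ANOVA screen of diversity indices against design factors
#'
#' Applies a one-way analysis of variance of each alpha-diversity index
#' against each design factor: size fraction, cultivation period,
#' surfactin treatment, and the change in algal cells. The continuous
#' algal-cell covariate is binned by sign into \code{decline} /
#' \code{stable} / \code{increase} groups (a one-way factorisation of a
#' covariate the screen treats categorically); samples with an undefined
#' change (0 h) are dropped for that factor. The model fit is the
#' classical \code{stats::aov} between/within decomposition.
#'
#' @param diversity output of [alphaDiversity()].
#' @param x the [OtuExperiment-class] providing the design columns.
#' @param factors colData columns to screen (default fraction, period,
#'   treatment, algal_cell_change).
#' @param indices which index columns to screen.
#' @param stableTol absolute algal-cell change treated as "stable"
#'   (default 0).
#' @return DataFrame with \code{response}, \code{factor}, \code{F},
#'   \code{p}, \code{df_between}, \code{df_within}.
#' @export
diversityAnova <- function(diversity, x,
        factors = c("fraction", "period", "treatment",
                    "algal_cell_change"),
        indices = c("richness", "shannon", "simpson", "evenness",
                    "chao1"),
        stableTol = 0) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd <- cd[diversity$sample_id, , drop = FALSE]
    out <- list()
    for (fac in factors) {
        if (!fac %in% colnames(cd))
            stop("factor '", fac, "' not in colData")
        g <- cd[[fac]]
        if (fac == "algal_cell_change")
            g <- ifelse(is.na(g), NA_character_,
                 ifelse(g > stableTol, "increase",
                 ifelse(g < -stableTol, "decline", "stable")))
        g <- factor(g)
        for (idx in indices) {
            v <- diversity[[idx]]
            ok <- !is.na(v) & !is.na(g) & is.finite(v)
            a <- oneWayAnova(v[ok], droplevels(g[ok]))
            out[[paste(idx, fac)]] <- S4Vectors::DataFrame(
                response = idx, factor = fac, F = a$F, p = a$p,
                df_between = a$df_between, df_within = a$df_within)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' One-way ANOVA of a numeric response on a grouping factor
#'
#' Classical between/within decomposition via \code{stats::aov}; the
#' degenerate all-identical-values case is reported as F = 0, p = 1
#' rather than NaN.
#'
#' @param values numeric response, one per observation.
#' @param groups factor of group labels.
#' @return list with \code{F}, \code{p}, \code{df_between},
#'   \code{df_within}.
#' @export
oneWayAnova <- function(values, groups) {
    groups <- factor(groups)
    if (nlevels(groups) < 2L)
        stop("need >= 2 groups")
    if (length(values) != length(groups))
        stop("values and groups differ in length")
    if (length(values) - nlevels(groups) < 1L)
        stop("no residual degrees of freedom")
    if (stats::var(values) == 0)           # all identical: F = 0 path
        return(list(F = 0, p = 1, df_between = nlevels(groups) - 1L,
                    df_within = length(values) - nlevels(groups)))
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1L]]
    Fv <- tab[["F value"]][1L]
    pv <- tab[["Pr(>F)"]][1L]
    if (is.na(Fv) || !is.finite(Fv)) {   # zero residual variance
        if (stats::var(values) == 0) {
            Fv <- 0
            pv <- 1
        }
    }
    list(F = Fv, p = pv,
         df_between = tab[["Df"]][1L], df_within = tab[["Df"]][2L])
}
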