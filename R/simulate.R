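#' Configuration for the synthetic size-fractionated community generator
#'
#' Builds a validated [SimulationConfig-class]. The defaults emulate the
#' sequenced design of a surfactin-exposure microcosm study: a control
#' (pure seawater) followed over 0--96 h, 0 and 2 mg/L surfactin
#' treatments over 24--96 h, and a 3 mg/L treatment sampled at 24 h only,
#' each with one free-living (FL) and one particle-attached (PA) sample
#' per cell -- 28 samples in all -- with per-sample read depths drawn from
#' the observed 10,819--94,695 range.
#'
#' Baseline relative abundances are log-normal with shape
#' \code{baseAbundanceSigma}, giving the skewed few-abundant /
#' many-rare structure typical of 16S OTU tables. Each OTU carries an
#' allocation logit \code{beta0} (drawn Normal(\code{beta0Mean},
#' \code{beta0Sd})); its probability of residing in the PA fraction of a
#' sample pair is \deqn{\pi_i(c, t) = \mathrm{logistic}(\beta_{0i} +
#' s \cdot c \cdot t)} with dose \eqn{c} in mg/L, time \eqn{t} in days and
#' \code{panShiftSlope} \eqn{s} in logit per (mg/L x day) -- the
#' treatment-by-time lifestyle shift from FL towards PA. Replicate-level
#' overdispersion is Dirichlet-multinomial with concentration
#' \code{overdispersion}; larger values approach a plain multinomial.
#'
#' @param nOtus number of OTUs (default 300).
#' @param treatments named numeric vector of surfactin doses in mg/L.
#' @param periods list of period vectors (hours), one per treatment, or a
#'   single vector recycled to every treatment.
#' @param nReplicates sample pairs per treatment x period cell (default 1).
#' @param depthRange min/max reads per sample (default c(10819, 94695)).
#' @param baseAbundanceSigma log-normal sigma of baselines (default 2).
#' @param panShiftSlope logit/(mg/L x day) lifestyle-shift slope
#'   (default 0.125).
#' @param beta0Mean,beta0Sd allocation-logit distribution (defaults -0.6,
#'   0.8: most OTUs prefer the FL fraction).
#' @param overdispersion Dirichlet concentration (default 2000).
#' @param classWeights named weights for partitioning OTUs among taxonomy
#'   class tokens.
#' @param seed integer seed (required for reproducibility).
#' @return A [SimulationConfig-class].
#' @seealso [simulateCommunity()], [readSimulationConfig()]
#' @export
simulationConfig <- function(nOtus = 300L,
        treatments = c(control = 0, S0 = 0, S2 = 2, S3 = 3),
        periods = list(control = c(0, 24, 48, 72, 96),
                       S0 = c(24, 48, 72, 96),
                       S2 = c(24, 48, 72, 96),
                       S3 = 24),
        nReplicates = 1L,
        depthRange = c(10819L, 94695L),
        baseAbundanceSigma = 2,
        panShiftSlope = 0.125,
        beta0Mean = -0.6,
        beta0Sd = 0.8,
        overdispersion = 2000,
        classWeights = c(Alphaproteobacteria = 0.25,
                         Gammaproteobacteria = 0.20,
                         Actinobacteria = 0.15,
                         Sphingobacteriia = 0.10,
                         Flavobacteriia = 0.10,
                         Cytophagia = 0.08,
                         Other = 0.12),
        seed = 1L) {
    if (!is.list(periods))
        periods <- rep(list(periods), length(treatments))
    if (is.null(names(periods)))
        names(periods) <- names(treatments)
    methods::new("SimulationConfig",
        nOtus = as.integer(nOtus),
        treatments = treatments,
        periods = periods[names(treatments)],
        nReplicates = as.integer(nReplicates),
        depthRange = as.integer(depthRange),
        baseAbundanceSigma = as.numeric(baseAbundanceSigma),
        panShiftSlope = as.numeric(panShiftSlope),
        beta0Mean = as.numeric(beta0Mean),
        beta0Sd = as.numeric(beta0Sd),
        overdispersion = as.numeric(overdispersion),
        classWeights = classWeights,
        seed = as.integer(seed))
}

#' Read a simulation configuration from YAML
#'
#' All values present in the file override [simulationConfig()] defaults
#' and are echoed to the console for provenance.
#'
#' @param path YAML file whose keys match [simulationConfig()] arguments.
#' @param quiet suppress the provenance echo.
#' @return A [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path, quiet = FALSE) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(simulationConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config keys: ", paste(bad, collapse = ", "))
    for (k in c("treatments", "classWeights"))
        if (!is.null(vals[[k]])) vals[[k]] <- unlist(vals[[k]])
    if (!quiet)
        for (k in names(vals))
            message("config: ", k, " = ",
                    paste(format(unlist(vals[[k]])), collapse = ", "))
    do.call(simulationConfig, vals)
}

#' Ground truth of a simulated community
#'
#' Draws the per-OTU latent parameters the generator conditions on:
#' baseline relative abundances (log-normal, normalised to sum to one),
#' allocation logits \code{beta0}, taxonomy class tokens, and empty
#' sensitivity flags. The sensitivity columns are filled by
#' [injectSensitiveOtus()]. Generator parameters are kept in
#' \code{S4Vectors::metadata()} of the returned DataFrame.
#'
#' @param config a [SimulationConfig-class].
#' @return DataFrame with one row per OTU: \code{otu_id}, \code{baseline},
#'   \code{beta0}, \code{class}, \code{sensitive}, \code{sensitivePeriod},
#'   \code{sensitiveFold}.
#' @export
makeGroundTruth <- function(config) {
    methods::validObject(config)
    set.seed(config@seed)
    n <- config@nOtus
    base <- stats::rlnorm(n, meanlog = 0, sdlog = config@baseAbundanceSigma)
    base <- base / sum(base)
    beta0 <- stats::rnorm(n, config@beta0Mean, config@beta0Sd)
    cls <- sample(names(config@classWeights), n, replace = TRUE,
                  prob = config@classWeights / sum(config@classWeights))
    truth <- S4Vectors::DataFrame(
        otu_id = sprintf("OTU_%04d", seq_len(n)),
        baseline = base,
        beta0 = beta0,
        class = cls,
        sensitive = rep(FALSE, n),
        sensitivePeriod = rep(NA_real_, n),
        sensitiveFold = rep(NA_real_, n))
    rownames(truth) <- truth$otu_id
    S4Vectors::metadata(truth) <- list(
        panShiftSlope = config@panShiftSlope,
        overdispersion = config@overdispersion)
    truth
}

#' Inject period-sensitive OTUs into a ground truth
#'
#' Marks \code{k} randomly chosen OTUs as sensitive: each gets one
#' randomly chosen cultivation period at which its expected relative
#' abundance is multiplied (or, with probability 1/2, divided) by
#' \code{fold} relative to all other periods. The flags and folds are
#' recorded so recovery experiments can compare detections against truth.
#'
#' @param truth output of [makeGroundTruth()].
#' @param k number of OTUs to perturb; \code{k = 0} returns \code{truth}
#'   unchanged.
#' @param fold fold change (> 1).
#' @param periods candidate periods (hours) to host the effect.
#' @param seed integer seed for the random choices.
#' @param candidates optional vector of OTU ids to draw from (defaults to
#'   all OTUs).
#' @return the truth DataFrame with sensitivity columns filled in.
#' @export
injectSensitiveOtus <- function(truth, k, fold,
                                periods = c(0, 24, 48, 72, 96), seed,
                                candidates = truth$otu_id) {
    if (fold <= 1)
        stop("fold must be > 1")
    if (k > length(candidates))
        stop("k exceeds the number of candidate OTUs")
    if (k == 0L)
        return(truth)
    if (missing(seed))
        stop("injectSensitiveOtus requires an explicit seed")
    set.seed(seed)
    pick <- sample(candidates, k)
    idx <- match(pick, truth$otu_id)
    truth$sensitive[idx] <- TRUE
    truth$sensitivePeriod[idx] <- sample(periods, k, replace = TRUE)
    up <- sample(c(TRUE, FALSE), k, replace = TRUE)
    truth$sensitiveFold[idx] <- ifelse(up, fold, 1 / fold)
    truth
}

#' Expected community composition at a cultivation period
#'
#' Applies the injected period effects to the baseline and renormalises;
#' this is the Dirichlet mean the generator uses for sample pairs at that
#' period.
#'
#' @param truth ground-truth DataFrame.
#' @param period cultivation period in hours.
#' @return numeric vector of expected relative abundances (sums to 1).
#' @export
expectedComposition <- function(truth, period) {
    p <- truth$baseline
    hit <- !is.na(truth$sensitivePeriod) & truth$sensitivePeriod == period
    p[hit] <- p[hit] * truth$sensitiveFold[hit]
    p / sum(p)
}

#' Expected particle-attached allocation probabilities
#'
#' \eqn{\pi_i(c, t) = \mathrm{logistic}(\beta_{0i} + s c t)}: the
#' probability that a read of OTU i in a sample pair at dose \code{dose}
#' (mg/L) and period \code{periodHours} falls in the PA fraction.
#'
#' @param truth ground-truth DataFrame.
#' @param dose surfactin dose in mg/L.
#' @param periodHours cultivation period in hours.
#' @return numeric vector of probabilities in (0, 1).
#' @export
panAllocation <- function(truth, dose, periodHours) {
    slope <- S4Vectors::metadata(truth)$panShiftSlope
    stats::plogis(truth$beta0 + slope * dose * periodHours / 24)
}

.rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) <= 0) {           # all-zero draw at extreme alphas
        g[which.max(alpha)] <- 1
    }
    g / sum(g)
}

.classPhylum <- c(
    Alphaproteobacteria = "Proteobacteria",
    Gammaproteobacteria = "Proteobacteria",
    Actinobacteria = "Actinobacteria",
    Sphingobacteriia = "Bacteroidetes",
    Flavobacteriia = "Bacteroidetes",
    Cytophagia = "Bacteroidetes")

#' Simulate a size-fractionated OTU experiment
#'
#' Generates one FL and one PA sample per (treatment, period, replicate)
#' cell of the design. For each pair, a pair-level composition is drawn
#' from a Dirichlet centred on [expectedComposition()] with concentration
#' \code{overdispersion}; total pair counts are multinomial at the summed
#' target depth (each sample's target depth drawn uniformly from
#' \code{depthRange}); and every OTU's reads are then split binomially
#' into the PA sample with probability \eqn{\pi_i(c, t)}
#' ([panAllocation()]), so the expected PA share of OTU i's mass in a
#' pair equals \eqn{\pi_i(c, t)} exactly. An algal-cell-change covariate
#' (cells/mL per 24 h, NA at 0 h) is simulated as a dose-dependent trend
#' with noise. A fixed config and truth give bit-identical output.
#'
#' @param config a [SimulationConfig-class].
#' @param truth optional ground truth (e.g. after
#'   [injectSensitiveOtus()]); default [makeGroundTruth()] on
#'   \code{config}.
#' @return list with \code{experiment}, an [OtuExperiment-class] whose
#'   colData carries \code{treatment}, \code{dose}, \code{period},
#'   \code{replicate}, \code{pair_id} and \code{algal_cell_change}, and
#'   \code{truth}, the ground-truth DataFrame.
#' @examples
#' sim <- simulateCommunity(simulationConfig(nOtus = 50, seed = 7))
#' sim$experiment
#' @export
simulateCommunity <- function(config, truth = NULL) {
    methods::validObject(config)
    if (is.null(truth))
        truth <- makeGroundTruth(config)
    stopifnot(nrow(truth) == config@nOtus)
    set.seed(config@seed + 101L)
    n <- config@nOtus
    cells <- do.call(rbind, lapply(names(config@treatments), function(tr)
        expand.grid(treatment = tr, period = config@periods[[tr]],
                    replicate = seq_len(config@nReplicates),
                    stringsAsFactors = FALSE)))
    counts <- matrix(0L, n, 2L * nrow(cells))
    md <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
        tr <- cells$treatment[i]
        dose <- config@treatments[[tr]]
        per <- cells$period[i]
        rep_i <- cells$replicate[i]
        p0 <- expectedComposition(truth, per)
        p <- .rdirichlet1(config@overdispersion * p0)
        dFL <- sample(config@depthRange[1L]:config@depthRange[2L], 1L)
        dPA <- sample(config@depthRange[1L]:config@depthRange[2L], 1L)
        tot <- stats::rmultinom(1L, dFL + dPA, p)[, 1L]
        pa <- stats::rbinom(n, tot, panAllocation(truth, dose, per))
        counts[, 2L * i - 1L] <- tot - pa
        counts[, 2L * i] <- pa
        acc <- if (per == 0) NA_real_ else
            stats::rnorm(1L, 1e5 * exp(-1.2 * dose) - 1.5e4 * dose -
                         (tr == "control") * 1e5, 1e4)
        md[[i]] <- data.frame(
            fraction = c("FL", "PA"), treatment = tr, dose = dose,
            period = per, replicate = rep_i,
            pair_id = sprintf("%s_T%03d_r%d", tr, per, rep_i),
            algal_cell_change = acc)
    }
    md <- do.call(rbind, md)
    md$sample_id <- sprintf("%s_%s", md$fraction, md$pair_id)
    rownames(counts) <- truth$otu_id
    colnames(counts) <- md$sample_id
    tax <- data.frame(otu_id = truth$otu_id,
        phylum = ifelse(truth$class %in% names(.classPhylum),
                        .classPhylum[truth$class], "Unclassified"),
        class = truth$class)
    keep <- colSums(counts) > 0   # guard against a fraction drawing 0 reads
    experiment <- OtuExperiment(counts[, keep, drop = FALSE],
                                md[keep, , drop = FALSE], taxonomy = tax)
    list(experiment = experiment, truth = truth)
}
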