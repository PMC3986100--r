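#' Simulation configuration for the synthetic-data module
#'
#' A \code{SimConfig} bundles every parameter of the synthetic-data
#' generators: the matched-pair expression cohort, the survival cohort whose
#' hazard depends on a planted signature score, and the aCGH probe tracks
#' with planted piecewise-constant segments.  Defaults mirror the study
#' design the package targets: 9 matched primary/metastasis pairs with 77
#' up- and 10 down-regulated genes planted at a mean paired log2 shift of
#' 1.2, survival cohorts of 400 platinum/taxane-treated patients, and
#' 200-probe chromosomes with 0.3 log10 copy-number steps.
#'
#' @slot nCases integer, number of matched primary/metastasis pairs.
#' @slot nGenes integer, size of the gene universe.
#' @slot nDeUp,nDeDown integers, planted up-/down-in-metastasis gene counts.
#' @slot deEffect numeric, mean paired log2 shift of planted genes.
#' @slot noiseSd numeric, residual log2 SD per sample.
#' @slot nPatients integer, survival cohort size.
#' @slot baselineHazard numeric, events per month at score 0.
#' @slot logHrPerPoint numeric, log hazard ratio per signature point.
#' @slot censorRate numeric in [0, 1), target fraction censored.
#' @slot nChroms,nProbesPerChrom integers, aCGH track dimensions.
#' @slot nSegments integer >= 0, planted breakpoints per chromosome.
#' @slot segmentEffect numeric, planted segment amplitude (log10 units).
#' @slot probeNoiseSd numeric, probe-level Gaussian noise SD (log10 units).
#' @slot outlierRate numeric in [0, 1), fraction of single-probe spikes.
#' @slot seed integer, master RNG seed; generators derive sub-streams from it.
#'
#' @seealso [simConfig()] for the validated constructor.
#' @export
setClass("SimConfig",
    slots = c(
        nCases = "integer", nGenes = "integer",
        nDeUp = "integer", nDeDown = "integer",
        deEffect = "numeric", noiseSd = "numeric",
        nPatients = "integer", baselineHazard = "numeric",
        logHrPerPoint = "numeric", censorRate = "numeric",
        nChroms = "integer", nProbesPerChrom = "integer",
        nSegments = "integer", segmentEffect = "numeric",
        probeNoiseSd = "numeric", outlierRate = "numeric",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    chkPos <- function(field) {
        v <- slot(object, field)
        if (length(v) != 1L || is.na(v) || v < 1L) {
            sprintf("'%s' must be a single integer >= 1", field)
        } else NULL
    }
    msgs <- unlist(lapply(
        c("nCases", "nGenes", "nPatients", "nChroms", "nProbesPerChrom"),
        chkPos
    ))
    if (object@nDeUp < 0L) msgs <- c(msgs, "'nDeUp' must be >= 0")
    if (object@nDeDown < 0L) msgs <- c(msgs, "'nDeDown' must be >= 0")
    if (object@nSegments < 0L) msgs <- c(msgs, "'nSegments' must be >= 0")
    if (object@nDeUp + object@nDeDown > object@nGenes) {
        msgs <- c(msgs, "'nDeUp' + 'nDeDown' must be <= 'nGenes'")
    }
    if (is.na(object@noiseSd) || object@noiseSd <= 0) {
        msgs <- c(msgs, "'noiseSd' must be > 0")
    }
    if (is.na(object@probeNoiseSd) || object@probeNoiseSd <= 0) {
        msgs <- c(msgs, "'probeNoiseSd' must be > 0")
    }
    if (is.na(object@censorRate) || object@censorRate < 0 ||
        object@censorRate >= 1) {
        msgs <- c(msgs, "'censorRate' must be in [0, 1)")
    }
    if (is.na(object@outlierRate) || object@outlierRate < 0 ||
        object@outlierRate >= 1) {
        msgs <- c(msgs, "'outlierRate' must be in [0, 1)")
    }
    if (is.na(object@deEffect) || object@deEffect < 0) {
        msgs <- c(msgs, "'deEffect' must be >= 0")
    }
    if (is.na(object@baselineHazard) || object@baselineHazard <= 0) {
        msgs <- c(msgs, "'baselineHazard' must be > 0")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' @param nCases Number of matched primary/metastasis pairs.
#' @param nGenes Gene universe size.
#' @param nDeUp,nDeDown Planted up-/down-regulated (in metastasis) gene counts.
#' @param deEffect Mean paired log2 fold change of planted genes.
#' @param noiseSd Residual log2 SD per sample.
#' @param nPatients Survival cohort size.
#' @param baselineHazard Baseline event hazard (events per month, score 0).
#' @param logHrPerPoint Log hazard ratio per signature point.
#' @param censorRate Target censoring fraction in [0, 1).
#' @param nChroms,nProbesPerChrom aCGH track dimensions.
#' @param nSegments Planted breakpoints per chromosome (0 = flat track).
#' @param segmentEffect Planted segment amplitude, log10 ratio units.
#' @param probeNoiseSd Probe-level noise SD, log10 ratio units.
#' @param outlierRate Fraction of probes receiving single-probe spikes.
#' @param seed Master RNG seed (integer).
#'
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nCases = 9, nGenes = 500, seed = 42)
#' cfg
#' @export
simConfig <- function(nCases = 9, nGenes = 1000, nDeUp = 77, nDeDown = 10,
                      deEffect = 1.2, noiseSd = 0.4,
                      nPatients = 400, baselineHazard = 0.02,
                      logHrPerPoint = 0.4, censorRate = 0.3,
                      nChroms = 3, nProbesPerChrom = 200,
                      nSegments = 2, segmentEffect = 0.3,
                      probeNoiseSd = 0.05, outlierRate = 0.02,
                      seed = 1) {
    obj <- new("SimConfig",
        nCases = as.integer(nCases), nGenes = as.integer(nGenes),
        nDeUp = as.integer(nDeUp), nDeDown = as.integer(nDeDown),
        deEffect = as.numeric(deEffect), noiseSd = as.numeric(noiseSd),
        nPatients = as.integer(nPatients),
        baselineHazard = as.numeric(baselineHazard),
        logHrPerPoint = as.numeric(logHrPerPoint),
        censorRate = as.numeric(censorRate),
        nChroms = as.integer(nChroms),
        nProbesPerChrom = as.integer(nProbesPerChrom),
        nSegments = as.integer(nSegments),
        segmentEffect = as.numeric(segmentEffect),
        probeNoiseSd = as.numeric(probeNoiseSd),
        outlierRate = as.numeric(outlierRate),
        seed = as.integer(seed)
    )
    validObject(obj)
    obj
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    cat(sprintf("  expression: %d pairs x %d genes, %d up / %d down planted at log2FC %.2f (noise SD %.2f)\n",
        object@nCases, object@nGenes, object@nDeUp, object@nDeDown,
        object@deEffect, object@noiseSd))
    cat(sprintf("  survival:   %d patients, baseline hazard %.3f, log HR/point %.2f, censor rate %.2f\n",
        object@nPatients, object@baselineHazard, object@logHrPerPoint,
        object@censorRate))
    cat(sprintf("  aCGH:       %d chrom x %d probes, %d breakpoints at +/-%.2f log10 (noise %.3f, outliers %.1f%%)\n",
        object@nChroms, object@nProbesPerChrom, object@nSegments,
        object@segmentEffect, object@probeNoiseSd, 100 * object@outlierRate))
    cat(sprintf("  seed: %d\n", object@seed))
})

#' Matched primary/metastasis expression cohort
#'
#' A \code{PairedExpressionCohort} is a
#' \linkS4class{SummarizedExperiment} holding a log2 gene-by-sample
#' expression matrix (assay \code{"log2expr"}) whose column data carry the
#' matched-pair design: a \code{case} identifier and a \code{tissue} label
#' (\code{"primary"} or \code{"metastasis"}).  Validity requires every case
#' to contribute exactly one sample of each tissue, unique gene identifiers,
#' and finite values.
#'
#' @seealso [pairedCohort()], [pairedDiffs()], [pairedDE()]
#' @export
setClass("PairedExpressionCohort", contains = "SummarizedExperiment")

setValidity("PairedExpressionCohort", function(object) {
    msgs <- character()
    if (!"log2expr" %in% assayNames(object)) {
        return("assay 'log2expr' is required")
    }
    m <- assay(object, "log2expr")
    if (anyNA(m) || any(!is.finite(m))) {
        msgs <- c(msgs, "expression values must be finite")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
        msgs <- c(msgs, "gene identifiers must be present and unique")
    }
    cd <- colData(object)
    if (!all(c("case", "tissue") %in% colnames(cd))) {
        return("colData must contain 'case' and 'tissue'")
    }
    if (!all(cd$tissue %in% c("primary", "metastasis"))) {
        msgs <- c(msgs, "tissue must be 'primary' or 'metastasis'")
    }
    tab <- table(cd$case, cd$tissue)
    if (nrow(tab) && (!all(dim(tab) == c(nrow(tab), 2L)) || any(tab != 1L))) {
        msgs <- c(msgs,
            "every case must have exactly one primary and one metastasis sample")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a matched-pair expression cohort
#'
#' @param values Numeric matrix of log2 expression, genes in rows (rownames
#'   required), samples in columns.
#' @param case Character vector of case identifiers, one per column.
#' @param tissue Character vector, \code{"primary"} or \code{"metastasis"},
#'   one per column.
#' @return A [PairedExpressionCohort-class].
#' @examples
#' m <- matrix(rnorm(20, 7), 5, 4,
#'     dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' pairedCohort(m, case = c("c1", "c1", "c2", "c2"),
#'     tissue = rep(c("primary", "metastasis"), 2))
#' @export
pairedCohort <- function(values, case, tissue) {
    values <- as.matrix(values)
    se <- SummarizedExperiment(
        assays = list(log2expr = values),
        colData = DataFrame(case = as.character(case),
            tissue = as.character(tissue),
            row.names = colnames(values))
    )
    obj <- new("PairedExpressionCohort", se)
    validObject(obj)
    obj
}

#' Median-vote metastatic gene signature
#'
#' An ordered set of signature genes, each with a metastasis direction
#' (\code{"up"}: higher in metastases than in matched primaries,
#' \code{"down"}: lower), plus the integer point threshold above which a
#' patient is called high-risk.  Cutpoints (per-gene cohort medians) are
#' never stored: they are recomputed within each evaluation cohort by
#' [scorePatients()].
#'
#' @slot genes Character vector of unique gene identifiers.
#' @slot directions Character vector, \code{"up"}/\code{"down"}, parallel to
#'   \code{genes}.
#' @slot threshold Integer; score strictly greater than this is high risk.
#' @seealso [metSignature()], [canonicalSignature()], [scorePatients()]
#' @export
setClass("MetSignature",
    slots = c(genes = "character", directions = "character",
        threshold = "integer")
)

setValidity("MetSignature", function(object) {
    msgs <- character()
    if (length(object@genes) < 1L) msgs <- c(msgs, "at least one gene required")
    if (anyDuplicated(object@genes)) msgs <- c(msgs, "gene ids must be unique")
    if (length(object@directions) != length(object@genes)) {
        msgs <- c(msgs, "'directions' must parallel 'genes'")
    }
    if (!all(object@directions %in% c("up", "down"))) {
        msgs <- c(msgs, "directions must be 'up' or 'down'")
    }
    k <- length(object@genes)
    if (length(object@threshold) != 1L || is.na(object@threshold) ||
        object@threshold < 0L || object@threshold >= k) {
        msgs <- c(msgs, "threshold must satisfy 0 <= threshold < k")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a median-vote signature
#'
#' @param genes Character vector of gene identifiers.
#' @param directions \code{"up"} or \code{"down"} per gene (recycled if
#'   length 1).
#' @param threshold Integer high-risk point threshold; the default
#'   \code{floor(k/2)} reproduces the "> 3 of 6 points" rule at k = 6.
#' @return A [MetSignature-class].
#' @examples
#' metSignature(c("CALB2", "IL7R"), directions = "up", threshold = 1)
#' @export
metSignature <- function(genes, directions = "up",
                         threshold = floor(length(genes) / 2)) {
    directions <- rep_len(directions, length(genes))
    obj <- new("MetSignature", genes = as.character(genes),
        directions = as.character(directions),
        threshold = as.integer(threshold))
    validObject(obj)
    obj
}

#' The canonical six-gene metastatic signature
#'
#' The six genes (CALB2, CYP1B1, EFTUD1, IL7R, RARRES2, TIMP3) that both
#' discriminate matched primary from metastatic serous ovarian tumors and
#' stratify overall survival in independent primary-tumor cohorts, with the
#' "> 3 points of 6" high-risk rule.  Directions default to
#' up-in-metastasis; they can be re-oriented per cohort from Cox coefficient
#' signs (see [randomSignature()]'s \code{directionMode = "cox"} analogue).
#'
#' @param directions Optional direction override, length 6.
#' @return A [MetSignature-class] with k = 6 and threshold 3.
#' @examples
#' canonicalSignature()
#' @export
canonicalSignature <- function(directions = rep("up", 6L)) {
    metSignature(
        genes = c("CALB2", "CYP1B1", "EFTUD1", "IL7R", "RARRES2", "TIMP3"),
        directions = directions,
        threshold = 3L
    )
}

setMethod("show", "MetSignature", function(object) {
    cat(sprintf("MetSignature of %d genes (high risk: score > %d)\n",
        length(object@genes), object@threshold))
    cat(paste0("  ", object@genes, " [", object@directions, "]\n"), sep = "")
})

#' Kaplan-Meier curve with median survival
#'
#' Product-limit survival estimate with Greenwood-based log-log confidence
#' bands and the Brookmeyer-Crowley style median confidence interval, as
#' returned by [kmFit()].
#'
#' @slot time Ordered unique observed times.
#' @slot surv Survival probability at each time.
#' @slot nRisk,nEvent At-risk and event counts at each time.
#' @slot n,nEvents Totals.
#' @slot median Median survival (smallest t with S(t) <= 0.5; \code{NA} if
#'   never reached).
#' @slot medianCI Length-2 numeric, 95% CI bounds for the median.
#' @export
setClass("KMCurve",
    slots = c(time = "numeric", surv = "numeric", nRisk = "numeric",
        nEvent = "numeric", n = "integer", nEvents = "integer",
        median = "numeric", medianCI = "numeric")
)

setMethod("show", "KMCurve", function(object) {
    cat(sprintf("KMCurve: n = %d, events = %d\n", object@n, object@nEvents))
    med <- if (is.na(object@median)) "not reached" else
        sprintf("%.3g (95%% CI %.3g-%.3g)", object@median,
            object@medianCI[1], object@medianCI[2])
    cat("  median survival:", med, "\n")
})

#' Random gene-set specificity null result
#'
#' Result of [empiricalNull()]: the observed log-rank p of a signature and
#' the distribution of log-rank p-values of random same-size gene sets
#' scored with the same median-vote rule, summarized as the proportion of
#' random sets that beat (strictly lower p) the observed signature.
#'
#' @slot observedP Log-rank p of the tested signature.
#' @slot randomP Numeric vector of random-set log-rank p-values.
#' @slot nRandom,nLower Counts of random sets and of strictly-lower p sets.
#' @slot empiricalP \code{nLower / nRandom} (or the add-one variant).
#' @slot mode Direction-assignment mode used for random sets.
#' @slot addOne Whether the (n+1)/(N+1) estimator was used.
#' @slot seed Seed used, \code{NA} if the caller managed the RNG.
#' @export
setClass("EmpiricalNullResult",
    slots = c(observedP = "numeric", randomP = "numeric",
        nRandom = "integer", nLower = "integer", empiricalP = "numeric",
        mode = "character", addOne = "logical", seed = "integer")
)

setMethod("show", "EmpiricalNullResult", function(object) {
    cat("EmpiricalNullResult\n")
    cat(sprintf("  observed log-rank p: %.4g\n", object@observedP))
    cat(sprintf("  random sets: %d (%d with lower p)\n",
        object@nRandom, object@nLower))
    cat(sprintf("  empirical p: %.4g [mode: %s%s]\n", object@empiricalP,
        object@mode, if (object@addOne) ", add-one" else ""))
})
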