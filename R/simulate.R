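# Synthetic-data generators. All generators are deterministic given
# cfg@seed; each draws from its own sub-stream so that, e.g., changing the
# number of probes never perturbs the expression cohort.

# Sub-stream splitting rule: streamSeed = (seed * 1009 + offset) mod (2^31-1),
# with a fixed offset per generator. Documented so runs are reproducible
# across generator call orders.
.streamSeed <- function(seed, offset) {
    as.integer((as.double(seed) * 1009 + offset) %% 2147483647)
}

#' Simulate a matched primary/metastasis expression cohort
#'
#' Generates a log2 gene-by-sample matrix for \code{nCases} matched pairs.
#' Each gene has a global mean level; each (gene, case) combination draws a
#' shared baseline, so the two samples of a case are correlated — the
#' structure a paired t-test exploits.  The first \code{nDeUp} genes gain
#' \code{+deEffect} log2 units in the metastasis sample, the next
#' \code{nDeDown} lose \code{deEffect}; all samples receive independent
#' Gaussian noise of SD \code{noiseSd}.
#'
#' @param cfg A [SimConfig-class].
#' @return A list with components \code{cohort}
#'   (a [PairedExpressionCohort-class] whose \code{rowData$truth} labels
#'   genes \code{"up"}, \code{"down"} or \code{"null"}) and \code{truth}
#'   (character vector of the same labels, named by gene).
#' @examples
#' sim <- simulatePairedCohort(simConfig(nGenes = 200, seed = 7))
#' table(SummarizedExperiment::rowData(sim$cohort)$truth)
#' @export
simulatePairedCohort <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    set.seed(.streamSeed(cfg@seed, 1L))
    nG <- cfg@nGenes; nC <- cfg@nCases
    genes <- sprintf("gene%04d", seq_len(nG))
    cases <- sprintf("case%02d", seq_len(nC))
    truth <- rep("null", nG)
    if (cfg@nDeUp > 0) truth[seq_len(cfg@nDeUp)] <- "up"
    if (cfg@nDeDown > 0) truth[cfg@nDeUp + seq_len(cfg@nDeDown)] <- "down"
    delta <- ifelse(truth == "up", cfg@deEffect,
        ifelse(truth == "down", -cfg@deEffect, 0))

    mu <- rnorm(nG, mean = 7, sd = 1.5)          # gene-level abundance
    base <- mu + matrix(rnorm(nG * nC, sd = 0.5), nG, nC)  # case baselines
    pri <- base + matrix(rnorm(nG * nC, sd = cfg@noiseSd), nG, nC)
    met <- base + delta + matrix(rnorm(nG * nC, sd = cfg@noiseSd), nG, nC)

    values <- cbind(pri, met)
    colnames(values) <- c(paste0(cases, "_P"), paste0(cases, "_M"))
    rownames(values) <- genes
    cohort <- pairedCohort(values,
        case = rep(cases, 2L),
        tissue = rep(c("primary", "metastasis"), each = nC))
    rowData(cohort)$truth <- truth
    list(cohort = cohort, truth = setNames(truth, genes))
}

#' Simulate a survival cohort driven by a planted signature score
#'
#' Each patient receives independent standard-normal log2 expression for the
#' signature genes (plus, optionally, \code{nNullGenes} null genes for
#' random-set experiments).  The true score is the median-vote score of
#' [scorePatients()]; event times are exponential with hazard
#' \code{baselineHazard * exp(logHrPerPoint * score)}, so the signature
#' effect is proportional-hazards by construction.  Censoring is an
#' independent exponential whose rate is solved so the expected censored
#' fraction equals \code{censorRate}.
#'
#' @param cfg A [SimConfig-class].
#' @param signature A [MetSignature-class]; its genes define the planted
#'   risk score.
#' @param nNullGenes Extra unrelated genes to include in the expression
#'   matrix (gene universe for null experiments): either a count (names
#'   are auto-generated) or a character vector of gene ids.
#' @return List with \code{clinical} (data.frame: patient, time, event,
#'   score, group, treated, residual_disease) and \code{expr} (gene x
#'   patient log2 matrix).
#' @examples
#' sig <- metSignature(paste0("g", 1:6))
#' sc <- simulateSurvivalCohort(simConfig(nPatients = 100, seed = 3), sig)
#' head(sc$clinical)
#' @export
simulateSurvivalCohort <- function(cfg, signature, nNullGenes = 0L) {
    stopifnot(is(cfg, "SimConfig"), is(signature, "MetSignature"))
    validObject(cfg)
    set.seed(.streamSeed(cfg@seed, 2L))
    sigGenes <- signatureGenes(signature)
    nullGenes <- if (is.character(nNullGenes)) {
        nNullGenes
    } else if (nNullGenes > 0) {
        sprintf("null%04d", seq_len(nNullGenes))
    } else character()
    if (any(sigGenes %in% nullGenes)) {
        stop("signature genes collide with the null gene names")
    }
    genes <- c(sigGenes, nullGenes)
    nP <- cfg@nPatients
    expr <- matrix(rnorm(length(genes) * nP), length(genes), nP,
        dimnames = list(genes, sprintf("pt%04d", seq_len(nP))))

    risk <- scorePatients(expr, signature)
    score <- risk$score
    hazard <- cfg@baselineHazard * exp(cfg@logHrPerPoint * score)
    evtTime <- rexp(nP, rate = hazard)
    if (cfg@censorRate > 0) {
        # solve E[P(C < T)] = censorRate for the censoring rate rc, with
        # P(C < T | h) = rc / (rc + h) under independent exponentials
        f <- function(rc) mean(rc / (rc + hazard)) - cfg@censorRate
        rc <- uniroot(f, lower = 1e-8, upper = 1e6 * max(hazard))$root
        cenTime <- rexp(nP, rate = rc)
    } else {
        cenTime <- rep(Inf, nP)
    }
    time <- pmin(evtTime, cenTime)
    event <- as.integer(evtTime <= cenTime)  # ties resolved as events
    clinical <- data.frame(
        patient = colnames(expr),
        time = time, event = event,
        score = score, group = risk$group,
        treated = TRUE,
        residual_disease = sample(c("none", "macro"), nP, replace = TRUE),
        stringsAsFactors = FALSE
    )
    list(clinical = clinical, expr = expr)
}

#' Simulate an aCGH probe track with planted segments
#'
#' Per chromosome, probes are evenly spaced and carry a piecewise-constant
#' true mean: \code{nSegments} breakpoints split the chromosome, alternating
#' between level 0 and \code{+/- segmentEffect} (random sign per aberrant
#' segment).  Gaussian probe noise of SD \code{probeNoiseSd} is added, and a
#' fraction \code{outlierRate} of probes receive single-probe spikes of
#' 5-8 noise-SDs with random sign (the target of SD-window smoothing).
#'
#' @param cfg A [SimConfig-class].
#' @return A list with \code{track} (a \linkS4class{GRanges}, mcols
#'   \code{probe} and \code{log10_ratio}), \code{truth} (per-chromosome list
#'   with \code{breakpoints} — probe index after which the mean changes —
#'   and \code{levels}) and \code{outliers} (indices of spiked probes).
#' @examples
#' pt <- simulateProbeTrack(simConfig(nChroms = 1, nSegments = 1, seed = 11))
#' pt$truth$chr1$breakpoints
#' @export
simulateProbeTrack <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    set.seed(.streamSeed(cfg@seed, 3L))
    nPr <- cfg@nProbesPerChrom
    probeWidth <- 60L
    spacing <- 5000L
    chroms <- paste0("chr", seq_len(cfg@nChroms))
    trackList <- list(); truth <- list(); outAll <- integer()
    offset <- 0L
    for (ch in chroms) {
        mu <- numeric(nPr)
        bps <- integer()
        if (cfg@nSegments > 0) {
            minLen <- max(5L, nPr %/% (4L * (cfg@nSegments + 1L)))
            ok <- FALSE
            for (try in seq_len(200L)) {
                cand <- sort(sample(seq(minLen, nPr - minLen), cfg@nSegments))
                if (cfg@nSegments == 1L ||
                    min(diff(cand)) >= minLen) { ok <- TRUE; break }
            }
            if (!ok) stop("could not place breakpoints with minimum spacing; ",
                "reduce 'nSegments'")
            bps <- cand
            bounds <- c(0L, bps, nPr)
            levels <- numeric(cfg@nSegments + 1L)
            for (j in seq_along(levels)) {
                levels[j] <- if (j %% 2L == 0L) {
                    sample(c(-1, 1), 1L) * cfg@segmentEffect
                } else 0
            }
            for (j in seq_along(levels)) {
                mu[(bounds[j] + 1L):bounds[j + 1L]] <- levels[j]
            }
        } else {
            levels <- 0
        }
        y <- mu + rnorm(nPr, sd = cfg@probeNoiseSd)
        out <- which(runif(nPr) < cfg@outlierRate)
        if (length(out)) {
            y[out] <- y[out] + sample(c(-1, 1), length(out), replace = TRUE) *
                runif(length(out), 5, 8) * cfg@probeNoiseSd
        }
        starts <- (seq_len(nPr) - 1L) * spacing + 1L
        trackList[[ch]] <- GRanges(ch,
            IRanges(start = starts, width = probeWidth),
            probe = sprintf("%s_p%04d", ch, seq_len(nPr)),
            log10_ratio = y)
        truth[[ch]] <- list(breakpoints = bps, levels = levels)
        outAll <- c(outAll, out + offset)
        offset <- offset + nPr
    }
    track <- suppressWarnings(do.call(c, unname(trackList)))
    list(track = track, truth = truth, outliers = outAll)
}

#' Simulate a paired staining table (Ki-67 / TUNEL style)
#'
#' Percent-positive staining for matched primary and metastasis tissues with
#' a log-normal within-case model: primary percentages are log-normal and
#' the metastasis value is the primary value times a multiplicative effect
#' with log-normal within-case scatter.  This is the data shape consumed by
#' [pairedLogTest()].
#'
#' @param nCases Number of matched cases.
#' @param effect Multiplicative metastasis/primary effect (1 = null).
#' @param cv Within-case coefficient of variation (log-scale SD approx).
#' @param meanPercent Geometric mean primary percentage.
#' @param assay Assay label recorded in the table.
#' @param seed RNG seed.
#' @return data.frame: case, tissue, percent, assay.
#' @examples
#' head(simulateStainingTable(nCases = 19, effect = 1.5, seed = 5))
#' @export
simulateStainingTable <- function(nCases = 19, effect = 1.5, cv = 0.4,
                                  meanPercent = 20, assay = "Ki-67",
                                  seed = 1) {
    set.seed(.streamSeed(seed, 4L))
    cases <- sprintf("case%02d", seq_len(nCases))
    pri <- rlnorm(nCases, meanlog = log(meanPercent), sdlog = 0.5)
    met <- pri * effect * rlnorm(nCases, meanlog = 0, sdlog = cv)
    pri <- pmin(pri, 100); met <- pmin(met, 100)
    data.frame(
        case = rep(cases, 2L),
        tissue = rep(c("primary", "metastasis"), each = nCases),
        percent = c(pri, met),
        assay = assay,
        stringsAsFactors = FALSE
    )
}
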