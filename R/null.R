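#' Draw a random gene set as a signature
#'
#' Samples k distinct genes uniformly without replacement from the universe
#' and wraps them as a [MetSignature-class] with the supplied threshold.
#' Directions are assigned per \code{directionMode}: \code{"random"} draws
#' each gene's direction uniformly; \code{"cox"} orients each gene by the
#' sign of its univariate Cox coefficient in a supplied training fit
#' (positive coefficient, i.e. hazard increases with expression, maps to
#' \code{"up"}).
#'
#' @param universe Character vector of candidate gene ids.
#' @param k Set size.
#' @param threshold High-risk threshold for the resulting signature.
#' @param directionMode \code{"random"} or \code{"cox"}.
#' @param coxSigns Named numeric vector of Cox coefficient signs (required
#'   for \code{directionMode = "cox"}).
#' @return A [MetSignature-class].
#' @examples
#' set.seed(1)
#' randomSignature(paste0("g", 1:50), k = 6)
#' @export
randomSignature <- function(universe, k, threshold = floor(k / 2),
                            directionMode = c("random", "cox"),
                            coxSigns = NULL) {
    directionMode <- match.arg(directionMode)
    if (length(universe) < k) {
        stop("gene universe (", length(universe),
            ") smaller than requested set size k = ", k)
    }
    genes <- sort(sample(universe, k))
    dirs <- switch(directionMode,
        random = sample(c("up", "down"), k, replace = TRUE),
        cox = {
            if (is.null(coxSigns) || !all(genes %in% names(coxSigns))) {
                stop("'coxSigns' must cover all sampled genes in cox mode")
            }
            ifelse(coxSigns[genes] >= 0, "up", "down")
        })
    metSignature(genes, dirs, threshold = threshold)
}

#' Random gene-set specificity null for a signature
#'
#' Quantifies how special a signature's survival separation is: the
#' observed log-rank p of the signature's high/low split is compared with
#' the p-values of \code{nRandom} random same-size gene sets scored with
#' the identical median-vote procedure on the same cohort.  The empirical p
#' is the number of random sets with \emph{strictly lower} log-rank p
#' divided by the number tested.  Random sets that yield a degenerate
#' grouping (all patients on one side of the threshold) are recorded with
#' p = 1 — they cannot beat the observed signature but still count in the
#' denominator.
#'
#' @param expr Gene x patient matrix containing the signature genes and the
#'   null universe.
#' @param time,event Survival data aligned to \code{expr} columns.
#' @param signature The observed [MetSignature-class].
#' @param nRandom Number of random sets (>= 1).
#' @param universe Genes to sample from (default: all rows of \code{expr}
#'   except the signature's own genes).
#' @param directionMode Direction assignment for random genes; see
#'   [randomSignature()].  In \code{"cox"} mode each universe gene is
#'   oriented once by the sign of its univariate Cox coefficient.
#' @param addOne Use the positively-biased estimator
#'   (nLower + 1) / (nRandom + 1) instead of nLower / nRandom.
#' @param seed Optional integer seed; \code{NA} leaves the caller's RNG
#'   state in charge.
#' @return An [EmpiricalNullResult-class].
#' @examples
#' sig <- metSignature(paste0("g", 1:6))
#' sc <- simulateSurvivalCohort(simConfig(nPatients = 80, seed = 9), sig,
#'     nNullGenes = 40)
#' empiricalNull(sc$expr, sc$clinical$time, sc$clinical$event, sig,
#'     nRandom = 200, seed = 1)
#' @export
empiricalNull <- function(expr, time, event, signature, nRandom,
                          universe = setdiff(rownames(expr),
                              signatureGenes(signature)),
                          directionMode = c("random", "cox"),
                          addOne = FALSE, seed = NA) {
    directionMode <- match.arg(directionMode)
    stopifnot(is.matrix(expr), nRandom >= 1)
    k <- length(signatureGenes(signature))
    if (length(universe) < k) {
        stop("universe smaller than signature size k = ", k)
    }
    if (!is.na(seed)) set.seed(as.integer(seed))

    thr <- riskThreshold(signature)
    prep <- .logrankPrep(time, event)
    # precompute per-gene strict above/below-median indicators once; every
    # random set's vote score is then a row sum over these
    allGenes <- union(signatureGenes(signature), universe)
    sub <- expr[allGenes, , drop = FALSE]
    med <- apply(sub, 1L, median)
    gtMed <- sub > med
    ltMed <- sub < med

    coxSigns <- NULL
    if (directionMode == "cox") {
        screen <- coxScreen(expr, time, event, genes = allGenes)
        coxSigns <- setNames(sign(ifelse(is.na(screen$coef), 1, screen$coef)),
            screen$gene)
    }

    scoreP <- function(genes, dirs) {
        up <- dirs == "up"
        sc <- colSums(gtMed[genes, , drop = FALSE] * up +
            ltMed[genes, , drop = FALSE] * (!up))
        hi <- sc > thr
        if (!any(hi) || all(hi)) return(1)
        unname(.logrankFromPrep(prep, hi)["p"])
    }

    observedP <- scoreP(signatureGenes(signature),
        signatureDirections(signature))
    randomP <- vapply(seq_len(nRandom), function(i) {
        genes <- sample(universe, k)
        dirs <- switch(directionMode,
            random = sample(c("up", "down"), k, replace = TRUE),
            cox = ifelse(coxSigns[genes] >= 0, "up", "down"))
        scoreP(genes, dirs)
    }, numeric(1))

    nLower <- sum(randomP < observedP)
    empiricalP <- if (addOne) (nLower + 1) / (nRandom + 1) else
        nLower / nRandom
    new("EmpiricalNullResult",
        observedP = observedP, randomP = randomP,
        nRandom = as.integer(nRandom), nLower = as.integer(nLower),
        empiricalP = empiricalP, mode = directionMode,
        addOne = addOne, seed = as.integer(seed))
}
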