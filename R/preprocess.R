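#' Quantile normalization
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of sorted value vectors.  Ties within a sample
#' receive the mean of the reference values over the tied rank span
#' (\code{limma::normalizeQuantiles} with \code{ties = TRUE}).  Idempotent.
#'
#' @param x A numeric matrix (genes x samples) or a
#'   [PairedExpressionCohort-class].
#' @return Object of the same class with normalized values; gene and sample
#'   order preserved.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
    if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
    if (anyNA(x) || any(!is.finite(x))) {
        stop("matrix contains non-finite entries")
    }
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "PairedExpressionCohort", function(x) {
    assay(x, "log2expr") <- quantileNormalize(assay(x, "log2expr"))
    x
})

#' Remove genes with consistently low signal
#'
#' Drops genes whose expression lies below the global lower quartile of the
#' whole matrix (linear-interpolation percentile, \code{type = 7}) in at
#' least a fraction \code{fraction} of samples.  The default
#' \code{fraction = 1} is the strict reading: below Q1 in \emph{every}
#' sample.  Comparison is strict (\code{<}), so a constant matrix loses no
#' genes.
#'
#' @param x A [PairedExpressionCohort-class].
#' @param fraction Fraction of samples that must be below Q1 for removal.
#' @return The filtered cohort; removed gene ids are recorded in
#'   \code{metadata(x)$removedGenes}.
#' @export
filterLowSignal <- function(x, fraction = 1) {
    stopifnot(is(x, "PairedExpressionCohort"), fraction > 0, fraction <= 1)
    m <- assay(x, "log2expr")
    if (nrow(m) == 0L) stop("empty expression matrix")
    q1 <- quantile(m, probs = 0.25, names = FALSE)
    below <- rowMeans(m < q1)
    drop <- below >= fraction
    out <- x[!drop, ]
    metadata(out)$removedGenes <- rownames(m)[drop]
    out
}

#' Paired differential expression between metastasis and primary
#'
#' For every gene, forms the per-case differences d = metastasis - primary
#' (log2), and tests mean(d) = 0 with a paired t-test: t = mean(d) /
#' (sd(d)/sqrt(n)), two-sided p from the t distribution with n - 1 df.
#' Genes with zero variance of d are assigned p = 1 (t reported \code{NA})
#' and kept in the Benjamini-Hochberg family so the multiple-testing family
#' size is not silently shrunk.  q-values are BH step-up over all tested
#' genes.  A gene passes the candidate filter when q < \code{qMax}, p <
#' \code{pMax} and |mean log2 FC| > \code{fcMin} simultaneously (defaults
#' 0.25 / 0.05 / 0.9).
#'
#' @param x A [PairedExpressionCohort-class] with >= 3 pairs.
#' @param fcMin Minimum absolute mean paired log2 fold change (strict).
#' @param pMax,qMax p-value and BH-FDR thresholds (strict).
#' @return data.frame, one row per gene: gene, meanLog2FC, t, df, p, q,
#'   direction (\code{"up"}/\code{"down"} by FC sign), passesFilter.
#' @examples
#' sim <- simulatePairedCohort(simConfig(nGenes = 100, seed = 2))
#' de <- pairedDE(sim$cohort)
#' head(de[order(de$p), ])
#' @export
pairedDE <- function(x, fcMin = 0.9, pMax = 0.05, qMax = 0.25) {
    stopifnot(is(x, "PairedExpressionCohort"))
    d <- pairedDiffs(x)
    n <- ncol(d)
    if (n < 3L) stop("paired differential expression needs >= 3 pairs")
    mn <- rowMeans(d)
    s <- apply(d, 1L, sd)
    tstat <- mn / (s / sqrt(n))
    p <- 2 * pt(-abs(tstat), df = n - 1L)
    zv <- s == 0
    tstat[zv] <- NA_real_
    p[zv] <- 1                               # degenerate rule: kept in BH m
    q <- p.adjust(p, method = "BH")
    res <- data.frame(
        gene = rownames(d),
        meanLog2FC = mn,
        t = tstat,
        df = n - 1L,
        p = p,
        q = q,
        direction = ifelse(mn > 0, "up", "down"),
        stringsAsFactors = FALSE,
        row.names = NULL
    )
    res$passesFilter <- res$q < qMax & res$p < pMax & abs(res$meanLog2FC) > fcMin
    attr(res, "thresholds") <- c(fcMin = fcMin, pMax = pMax, qMax = qMax)
    res
}

#' Extract the ordered differential-expression candidate list
#'
#' Genes passing the paired-DE filter, annotated with their metastasis
#' direction and sorted by ascending p (ties broken by gene id for
#' determinism).
#'
#' @param de A data.frame from [pairedDE()].
#' @return data.frame: gene, direction, meanLog2FC, p, q.  Empty (with a
#'   warning) when no gene passes.
#' @export
candidateList <- function(de) {
    stopifnot(all(c("gene", "p", "passesFilter") %in% colnames(de)))
    keep <- de[de$passesFilter, , drop = FALSE]
    if (nrow(keep) == 0L) {
        warning("no gene passes the differential-expression filter")
        return(data.frame(gene = character(), direction = character(),
            meanLog2FC = numeric(), p = numeric(), q = numeric(),
            stringsAsFactors = FALSE))
    }
    keep <- keep[order(keep$p, keep$gene), , drop = FALSE]
    rownames(keep) <- NULL
    keep[, c("gene", "direction", "meanLog2FC", "p", "q")]
}
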