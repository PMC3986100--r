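# Staining statistics (Ki-67 proliferation index, TUNEL apoptotic index)
# and the Ki-67-delta expression correlation ranking.

.stainingPairs <- function(table) {
    stopifnot(all(c("case", "tissue", "percent") %in% colnames(table)))
    cases <- intersect(table$case[table$tissue == "primary"],
        table$case[table$tissue == "metastasis"])
    pri <- table$percent[match(paste0(cases, ".primary"),
        paste0(table$case, ".", table$tissue))]
    met <- table$percent[match(paste0(cases, ".metastasis"),
        paste0(table$case, ".", table$tissue))]
    list(cases = cases, primary = pri, metastasis = met)
}

#' Paired t-test of staining percentages after log transformation
#'
#' Percent-positive staining indices are approximately log-normal, so the
#' matched metastasis-vs-primary comparison is a paired t-test on
#' log-transformed percentages (natural log; the statistic is base
#' invariant).  Shapiro-Wilk normality p-values of the raw and of the
#' log-scale paired differences are reported so the transform can be
#' justified per dataset.  Zero percentages are replaced by half the
#' smallest positive observed value before the log (flagged in the
#' output).  If all pairs are identical the test is degenerate and
#' reported as no difference (p = 1).
#'
#' @param table data.frame with columns \code{case}, \code{tissue}
#'   (\code{"primary"}/\code{"metastasis"}) and \code{percent} (0-100).
#' @return List: n (complete pairs), nHigherInMet (cases with metastasis
#'   strictly higher, raw scale), t, p, normalityPRaw, normalityPLog,
#'   zerosReplaced.
#' @examples
#' tab <- simulateStainingTable(nCases = 19, effect = 1.5, seed = 8)
#' pairedLogTest(tab)
#' @export
pairedLogTest <- function(table) {
    pp <- .stainingPairs(table)
    n <- length(pp$cases)
    if (n < 3L) stop("need >= 3 complete pairs")
    if (any(c(pp$primary, pp$metastasis) < 0) ||
        any(c(pp$primary, pp$metastasis) > 100)) {
        stop("percentages must lie in [0, 100]")
    }
    vals <- c(pp$primary, pp$metastasis)
    zeros <- vals == 0
    if (any(zeros)) {
        repl <- min(vals[vals > 0]) / 2
        vals[zeros] <- repl
    }
    pri <- vals[seq_len(n)]
    met <- vals[n + seq_len(n)]
    dRaw <- pp$metastasis - pp$primary
    dLog <- log(met) - log(pri)
    swSafe <- function(x) {
        if (length(unique(x)) < 3L) return(NA_real_)
        tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
    }
    if (sd(dLog) == 0) {
        t <- 0; p <- 1                      # degenerate: no difference
    } else {
        tt <- t.test(log(met), log(pri), paired = TRUE)
        t <- unname(tt$statistic); p <- tt$p.value
    }
    list(
        n = n,
        nHigherInMet = sum(pp$metastasis > pp$primary),
        t = t, p = p,
        normalityPRaw = swSafe(dRaw),
        normalityPLog = swSafe(dLog),
        zerosReplaced = sum(zeros)
    )
}

#' Genes whose expression change tracks the change in Ki-67 staining
#'
#' For every gene, the Pearson correlation across cases between the paired
#' expression change (metastasis - primary, log2) and the paired change in
#' Ki-67 percent-positive staining (raw percent scale by default; the
#' ranking is invariant to affine transforms of the staining delta).  Genes
#' are ranked by descending signed r and the top \code{topN} returned.
#' Genes with zero-variance expression change are excluded (r undefined).
#'
#' @param cohort A [PairedExpressionCohort-class].
#' @param table Staining data.frame (case/tissue/percent), e.g. Ki-67.
#' @param topN Number of genes to return (default 250).
#' @param logDelta Use log-scale staining deltas instead of raw percents.
#' @return data.frame gene/r, ranked; attribute \code{"minR"} records the
#'   smallest correlation attained in the returned list.
#' @export
ki67CorrelatedGenes <- function(cohort, table, topN = 250, logDelta = FALSE) {
    stopifnot(is(cohort, "PairedExpressionCohort"))
    pp <- .stainingPairs(table)
    dExprAll <- pairedDiffs(cohort)
    shared <- intersect(colnames(dExprAll), pp$cases)
    if (length(shared) < 4L) {
        stop("need >= 4 cases shared between cohort and staining table")
    }
    idx <- match(shared, pp$cases)
    dK <- if (logDelta) {
        log(pp$metastasis[idx]) - log(pp$primary[idx])
    } else {
        pp$metastasis[idx] - pp$primary[idx]
    }
    dE <- dExprAll[, shared, drop = FALSE]
    vr <- apply(dE, 1L, sd)
    excluded <- rownames(dE)[vr == 0]
    dE <- dE[vr > 0, , drop = FALSE]
    r <- as.vector(cor(t(dE), dK))
    res <- data.frame(gene = rownames(dE), r = r, stringsAsFactors = FALSE)
    res <- res[order(-res$r, res$gene), , drop = FALSE]
    if (topN > nrow(res)) {
        warning("topN (", topN, ") exceeds available genes (", nrow(res),
            "); returning the full ranked list")
        topN <- nrow(res)
    }
    res <- head(res, topN)
    rownames(res) <- NULL
    attr(res, "minR") <- min(res$r)
    attr(res, "excluded") <- excluded
    res
}

#' Cluster samples on a signature's expression and score tissue separation
#'
#' Restricts the expression matrix to the signature genes, clusters samples
#' with 1 - Pearson distance and average linkage, cuts the tree into two
#' clusters, and reports how well the cut reproduces the primary/metastasis
#' labels: the separation fraction is the best achievable agreement over
#' the two cluster-to-label assignments.
#'
#' @param cohort A [PairedExpressionCohort-class] (>= 4 samples).
#' @param signature A [MetSignature-class]; only its genes are used.
#' @return List: \code{hclust}, \code{clusters} (two-cluster cut),
#'   \code{separation} (fraction of samples correctly separated, >= 0.5).
#' @export
clusterExpression <- function(cohort, signature) {
    stopifnot(is(cohort, "PairedExpressionCohort"),
        is(signature, "MetSignature"))
    if (ncol(cohort) < 4L) stop("need >= 4 samples")
    genes <- signatureGenes(signature)
    missing <- setdiff(genes, rownames(cohort))
    if (length(missing)) {
        stop("signature genes absent from cohort: ",
            paste(missing, collapse = ", "))
    }
    m <- exprValues(cohort)[genes, , drop = FALSE]
    v <- apply(m, 2L, sd)
    if (any(v == 0)) {
        warning("excluding zero-variance sample(s): ",
            paste(colnames(m)[v == 0], collapse = ", "))
        keep <- v > 0
        m <- m[, keep, drop = FALSE]
    }
    d <- as.dist(1 - cor(m))
    hc <- hclust(d, method = "average")
    cl <- cutree(hc, k = 2L)
    lab <- tissueLabels(cohort)[match(names(cl), colnames(cohort))]
    agree <- mean((cl == 1L) == (lab == "metastasis"))
    list(hclust = hc, clusters = cl, separation = max(agree, 1 - agree))
}
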