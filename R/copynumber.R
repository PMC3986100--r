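# aCGH analysis: SD-window outlier smoothing, circular binary segmentation,
# gene-level copy-number scoring, metastasis-specific recurrent CNA calls,
# and CNA-profile clustering.

.checkTrack <- function(track) {
    stopifnot(is(track, "GRanges"))
    if (!"log10_ratio" %in% colnames(mcols(track))) {
        stop("track must carry an mcols column 'log10_ratio'")
    }
    if (any(!is.finite(mcols(track)$log10_ratio))) {
        stop("probe log10 ratios must be finite")
    }
    if (is.unsorted(order(as.integer(seqnames(track)),
            GenomicRanges::start(track)))) {
        track <- GenomicRanges::sort(track)
    }
    track
}

#' Smooth single-probe outliers in an aCGH track
#'
#' Standard-deviation window smoothing: a probe whose log10 ratio deviates
#' by more than \code{nsd} track-SDs from the median of its +/-\code{region}
#' probe window (same chromosome, truncated at boundaries) is pulled back to
#' that window median plus/minus \code{nsd} SDs; all other probes are
#' untouched.  The track SD is estimated robustly (MAD) so that the spikes
#' being removed do not inflate their own detection threshold.
#'
#' @param track \linkS4class{GRanges} with mcols \code{log10_ratio}.
#' @param region Half-width of the probe window (default 10).
#' @param nsd SD multiple defining an outlier (default 3).
#' @return The track with smoothed \code{log10_ratio}; indices of modified
#'   probes in \code{metadata}-style attribute \code{"smoothed"}.
#' @examples
#' pt <- simulateProbeTrack(simConfig(nChroms = 1, seed = 2))
#' sm <- smoothOutliers(pt$track)
#' @export
smoothOutliers <- function(track, region = 10, nsd = 3) {
    track <- .checkTrack(track)
    y <- mcols(track)$log10_ratio
    sdT <- mad(y)
    if (sdT == 0) sdT <- sd(y)
    changed <- integer()
    if (sdT > 0) {
        chrom <- as.character(seqnames(track))
        for (ch in unique(chrom)) {
            idx <- which(chrom == ch)
            yc <- y[idx]
            n <- length(yc)
            for (i in seq_len(n)) {
                lo <- max(1L, i - region)
                hi <- min(n, i + region)
                medW <- median(yc[lo:hi])
                dev <- y[idx[i]] - medW
                if (abs(dev) > nsd * sdT) {
                    y[idx[i]] <- medW + sign(dev) * nsd * sdT
                    changed <- c(changed, idx[i])
                }
            }
        }
    }
    mcols(track)$log10_ratio <- y
    attr(track, "smoothed") <- changed
    track
}

# Maximal arc t-statistic of circular binary segmentation on one segment.
# Returns the statistic, the arc start index and arc length.
.maxArcT <- function(x, minWidth = 2L) {
    n <- length(x)
    sdx <- sd(x)
    if (n < 2L * minWidth || sdx == 0) {
        return(list(stat = 0, i0 = NA_integer_, k = NA_integer_))
    }
    cs <- c(0, cumsum(x))
    tot <- cs[n + 1L]
    best <- -Inf; bi <- NA_integer_; bk <- NA_integer_
    for (k in minWidth:(n - minWidth)) {
        win <- cs[(k + 1L):(n + 1L)] - cs[1L:(n - k + 1L)]
        z <- abs(win / k - (tot - win) / (n - k)) / sqrt(1 / k + 1 / (n - k))
        j <- which.max(z)
        if (z[j] > best) { best <- z[j]; bi <- j; bk <- k }
    }
    list(stat = best / sdx, i0 = bi, k = bk)
}

# Permutation p-value of the maximal arc statistic, with early termination
# once significance can no longer be reached.
.cbsSplitP <- function(x, statObs, nPerm, alpha, minWidth) {
    needed <- ceiling(alpha * nPerm)
    count <- 0L
    for (b in seq_len(nPerm)) {
        if (.maxArcT(sample(x), minWidth)$stat >= statObs) {
            count <- count + 1L
            if (count >= needed) return(1)  # cannot be < alpha any more
        }
    }
    count / nPerm
}

.cbsOneChrom <- function(x, alpha, nPerm, minWidth) {
    segmentsOf <- function(lo, hi) {
        n <- hi - lo + 1L
        if (n < 2L * minWidth) return(cbind(lo, hi))
        arc <- .maxArcT(x[lo:hi], minWidth)
        if (!is.finite(arc$stat) || arc$stat <= 0) return(cbind(lo, hi))
        p <- .cbsSplitP(x[lo:hi], arc$stat, nPerm, alpha, minWidth)
        if (p >= alpha) return(cbind(lo, hi))
        aLo <- lo + arc$i0 - 1L
        aHi <- aLo + arc$k - 1L
        pieces <- list()
        if (aLo > lo) pieces <- c(pieces, list(segmentsOf(lo, aLo - 1L)))
        pieces <- c(pieces, list(segmentsOf(aLo, aHi)))
        if (aHi < hi) pieces <- c(pieces, list(segmentsOf(aHi + 1L, hi)))
        do.call(rbind, pieces)
    }
    segmentsOf(1L, length(x))
}

#' Circular binary segmentation of a probe track
#'
#' Recursive changepoint search: within each current segment the
#' two-sample t-like statistic is maximized over all contiguous arcs (the
#' complement being the two joined ends of the circularized segment); the
#' best split is accepted when its permutation p-value, from \code{nPerm}
#' random relabelings of the probe values, is below \code{alpha}.  Accepted
#' arcs split the segment into up to three pieces, each segmented
#' recursively; segments shorter than \code{2 * minWidth} probes are never
#' split.  Run [smoothOutliers()] first so single-probe spikes do not fake
#' breakpoints.
#'
#' @param track \linkS4class{GRanges} with mcols \code{log10_ratio}
#'   (ideally smoothed).
#' @param alpha Split acceptance level (default 0.05).
#' @param nPerm Number of permutations per split test (>= 100).
#' @param minWidth Minimum arc width in probes.
#' @param seed Optional integer seed for the permutation stream.
#' @return \linkS4class{GRanges} of non-overlapping segments covering the
#'   probe extent per chromosome, with mcols \code{n_probes} and
#'   \code{seg_mean}.
#' @examples
#' pt <- simulateProbeTrack(simConfig(nChroms = 1, nSegments = 1, seed = 6))
#' segmentCBS(pt$track, nPerm = 100, seed = 1)
#' @export
segmentCBS <- function(track, alpha = 0.05, nPerm = 1000, minWidth = 2,
                       seed = NA) {
    track <- .checkTrack(track)
    if (nPerm < 100) stop("'nPerm' must be >= 100")
    if (!is.na(seed)) set.seed(as.integer(seed))
    y <- mcols(track)$log10_ratio
    chrom <- as.character(seqnames(track))
    out <- list()
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        segIdx <- .cbsOneChrom(y[idx], alpha, nPerm, as.integer(minWidth))
        for (r in seq_len(nrow(segIdx))) {
            probes <- idx[segIdx[r, 1L]:segIdx[r, 2L]]
            out[[length(out) + 1L]] <- data.frame(
                chrom = ch,
                start = min(GenomicRanges::start(track)[probes]),
                end = max(GenomicRanges::end(track)[probes]),
                n_probes = length(probes),
                seg_mean = mean(y[probes])
            )
        }
    }
    df <- do.call(rbind, out)
    GRanges(df$chrom, IRanges(df$start, df$end),
        n_probes = df$n_probes, seg_mean = df$seg_mean)
}

#' Gene-level copy number from segmented probes
#'
#' Each probe inherits the mean of the segment containing it; the gene
#' score is the average of these segmented values over all probes whose
#' interval overlaps the gene region (any overlap counts).  Genes covered
#' by fewer than \code{minProbes} probes are dropped, as are genes on
#' chromosomes absent from the track (with a message).
#'
#' @param segments Segment \linkS4class{GRanges} from [segmentCBS()].
#' @param track Probe \linkS4class{GRanges} (the same probes that were
#'   segmented).
#' @param genes \linkS4class{GRanges} of gene models (e.g. from
#'   [readGeneModels()]); gene ids from \code{mcols(genes)$name} or
#'   \code{names(genes)}.
#' @param minProbes Minimum overlapping probes per reported gene.
#' @return data.frame: gene, nProbes, log10CN.
#' @export
geneCopyNumber <- function(segments, track, genes, minProbes = 3) {
    track <- .checkTrack(track)
    stopifnot(is(segments, "GRanges"), is(genes, "GRanges"))
    ids <- if (!is.null(mcols(genes)$name)) mcols(genes)$name else
        names(genes)
    if (is.null(ids)) stop("gene models need names ('name' mcol or names())")
    segOf <- GenomicRanges::findOverlaps(track, segments, select = "first")
    if (anyNA(segOf)) stop("some probes fall outside every segment")
    probeVal <- mcols(segments)$seg_mean[segOf]
    ov <- findOverlaps(genes, track)
    cnt <- tabulate(queryHits(ov), nbins = length(genes))
    onTrack <- as.character(seqnames(genes)) %in%
        unique(as.character(seqnames(track)))
    if (any(!onTrack)) {
        message("geneCopyNumber: ", sum(!onTrack),
            " gene(s) on chromosomes absent from the track; dropped")
    }
    sums <- rep(0, length(genes))
    agg <- rowsum(probeVal[subjectHits(ov)], queryHits(ov))
    sums[as.integer(rownames(agg))] <- agg[, 1L]
    keep <- cnt >= minProbes
    data.frame(
        gene = ids[keep],
        nProbes = cnt[keep],
        log10CN = sums[keep] / cnt[keep],
        stringsAsFactors = FALSE,
        row.names = NULL
    )
}

#' Recurrent metastasis-specific copy-number aberrations
#'
#' Calls a gene amplified when its gene-level log10 copy number exceeds
#' \code{ampThresh} and lost below \code{-ampThresh}.  Within a case, a
#' call is tissue-specific when present in one tissue and absent (same
#' direction) in the matched tissue; a gene is reported when such
#' tissue-specific calls recur in at least \code{minCases} cases \emph{and}
#' its across-sample Pearson correlation between expression and copy
#' number exceeds \code{rMin}.  Genes without expression data are reported
#' with \code{r = NA} and flagged uncorrelatable.
#'
#' @param cn Gene x sample numeric matrix of gene-level log10 copy numbers
#'   (\code{NA} where a gene had too few probes in a sample).
#' @param case,tissue Character vectors labelling the columns of \code{cn}
#'   (tissue in \code{c("primary", "metastasis")}).
#' @param expr Optional gene x sample log2 expression matrix with the same
#'   columns as \code{cn}.
#' @param ampThresh Amplification/loss threshold on log10 ratio.
#' @param rMin Minimum expression-copy number Pearson correlation.
#' @param minCases Minimum recurrent cases.
#' @return data.frame: gene, direction (\code{"amplified"}/\code{"lost"}),
#'   specificity (\code{"met-only"}/\code{"primary-only"}), nCases, r,
#'   correlated.
#' @export
metSpecificCNAs <- function(cn, case, tissue, expr = NULL,
                            ampThresh = 0.1, rMin = 0.7, minCases = 2) {
    stopifnot(is.matrix(cn), length(case) == ncol(cn),
        length(tissue) == ncol(cn),
        all(tissue %in% c("primary", "metastasis")))
    cases <- unique(case)
    if (length(cases) < minCases) {
        stop("need >= ", minCases, " cases with both tissues")
    }
    met <- cn[, match(paste0(cases, ".metastasis"),
        paste0(case, ".", tissue)), drop = FALSE]
    pri <- cn[, match(paste0(cases, ".primary"),
        paste0(case, ".", tissue)), drop = FALSE]
    rows <- list()
    for (dir in c("amplified", "lost")) {
        callM <- if (dir == "amplified") met > ampThresh else met < -ampThresh
        callP <- if (dir == "amplified") pri > ampThresh else pri < -ampThresh
        callM[is.na(callM)] <- FALSE
        callP[is.na(callP)] <- FALSE
        metOnly <- rowSums(callM & !callP)
        priOnly <- rowSums(callP & !callM)
        for (spec in c("met-only", "primary-only")) {
            nC <- if (spec == "met-only") metOnly else priOnly
            hit <- which(nC >= minCases)
            for (i in hit) {
                rows[[length(rows) + 1L]] <- data.frame(
                    gene = rownames(cn)[i], direction = dir,
                    specificity = spec, nCases = nC[i],
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows)) {
        return(data.frame(gene = character(), direction = character(),
            specificity = character(), nCases = integer(), r = numeric(),
            correlated = logical(), stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, rows)
    res$r <- NA_real_
    for (i in seq_len(nrow(res))) {
        g <- res$gene[i]
        if (!is.null(expr) && g %in% rownames(expr)) {
            res$r[i] <- suppressWarnings(
                cor(expr[g, ], cn[g, ], use = "pairwise.complete.obs"))
        }
    }
    res$correlated <- !is.na(res$r) & res$r > rMin
    keep <- res$correlated | is.na(res$r)
    res <- res[keep, , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Hierarchical clustering of copy-number profiles
#'
#' Average-linkage agglomerative clustering of samples with distance
#' 1 - Pearson correlation between gene-level copy-number profiles.  When
#' case/tissue labels are supplied, reports for each case whether its
#' primary and metastasis samples merge with each other before any other
#' sample (a cherry in the dendrogram) — the "pairs cluster together"
#' statistic.
#'
#' @param cn Gene x sample matrix (>= 3 samples).
#' @param case,tissue Optional column labels for pair reporting.
#' @return List: \code{hclust} (the tree), \code{dist} (distance matrix),
#'   \code{excluded} (zero-variance samples dropped with a warning),
#'   \code{pairs} (data.frame case/coClustered, when labels given),
#'   \code{nCoClustered}.
#' @export
clusterCNAProfiles <- function(cn, case = NULL, tissue = NULL) {
    stopifnot(is.matrix(cn))
    v <- apply(cn, 2L, function(x) sd(x, na.rm = TRUE))
    excluded <- colnames(cn)[is.na(v) | v == 0]
    if (length(excluded)) {
        warning("excluding zero-variance sample(s): ",
            paste(excluded, collapse = ", "))
        keep <- !(colnames(cn) %in% excluded)
        cn <- cn[, keep, drop = FALSE]
        if (!is.null(case)) case <- case[keep]
        if (!is.null(tissue)) tissue <- tissue[keep]
    }
    if (ncol(cn) < 3L) stop("clustering needs >= 3 usable samples")
    d <- as.dist(1 - cor(cn, use = "pairwise.complete.obs"))
    hc <- hclust(d, method = "average")
    out <- list(hclust = hc, dist = d, excluded = excluded)
    if (!is.null(case) && !is.null(tissue)) {
        # cherries: merge steps joining two singleton leaves
        cherries <- hc$merge[hc$merge[, 1L] < 0 & hc$merge[, 2L] < 0, ,
            drop = FALSE]
        cherryPairs <- apply(-cherries, 1L, sort, simplify = FALSE)
        cases <- unique(case)
        co <- vapply(cases, function(cs) {
            i <- which(case == cs & tissue == "primary")
            j <- which(case == cs & tissue == "metastasis")
            if (length(i) != 1L || length(j) != 1L) return(NA)
            any(vapply(cherryPairs, function(p)
                identical(p, sort(c(i, j))), logical(1)))
        }, logical(1))
        out$pairs <- data.frame(case = cases, coClustered = co,
            stringsAsFactors = FALSE)
        out$nCoClustered <- sum(co, na.rm = TRUE)
    }
    out
}
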