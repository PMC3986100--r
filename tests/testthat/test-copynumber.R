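# aCGH smoothing, CBS segmentation, gene-level copy number,
# metastasis-specific CNAs, and profile clustering

flatTrack <- function(y, chrom = "chr1") {
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = (seq_along(y) - 1L) * 1000L + 1L,
            width = 60L),
        probe = paste0("p", seq_along(y)), log10_ratio = y)
}

test_that("outlier smoothing fixes spikes and nothing else", {
    # constant track: unchanged
    tr <- flatTrack(rep(0.1, 50))
    expect_equal(S4Vectors::mcols(smoothOutliers(tr))$log10_ratio,
        rep(0.1, 50))
    # single +10 spike in near-flat noise is pulled to the window median
    set.seed(4)
    y <- rnorm(100, 0, 0.05); y[50] <- 10
    sm <- smoothOutliers(flatTrack(y))
    ysm <- S4Vectors::mcols(sm)$log10_ratio
    expect_lt(abs(ysm[50]), 1)
    expect_equal(ysm[-50], y[-50])
    # no point beyond nsd SDs: identity
    y2 <- rnorm(80, 0, 0.05)
    y2 <- pmin(pmax(y2, -0.1), 0.1)
    expect_equal(S4Vectors::mcols(smoothOutliers(flatTrack(y2)))$log10_ratio,
        y2)
})

test_that("a constant-mean chromosome is one segment", {
    set.seed(10)
    tr <- flatTrack(rnorm(150, 0, 0.05))
    segs <- segmentCBS(tr, nPerm = 200, seed = 1)
    expect_equal(length(segs), 1L)
    expect_equal(S4Vectors::mcols(segs)$n_probes, 150)
})

test_that("a planted breakpoint is located and levels recovered", {
    cfg <- simConfig(nChroms = 1, nSegments = 1, segmentEffect = 0.3,
        probeNoiseSd = 0.05, outlierRate = 0, seed = 44)
    pt <- simulateProbeTrack(cfg)
    segs <- segmentCBS(smoothOutliers(pt$track), nPerm = 200, seed = 2)
    expect_equal(length(segs), 2L)
    bpTruth <- pt$truth$chr1$breakpoints
    bpFound <- S4Vectors::mcols(segs)$n_probes[1]
    expect_lte(abs(bpFound - bpTruth), 2L)
    lv <- pt$truth$chr1$levels
    se <- cfg@probeNoiseSd / sqrt(min(S4Vectors::mcols(segs)$n_probes))
    expect_lt(max(abs(S4Vectors::mcols(segs)$seg_mean - lv)), 3 * se)
})

test_that("segment means reconstruct the track mean exactly", {
    pt <- simulateProbeTrack(simConfig(nChroms = 2, nSegments = 2, seed = 9))
    sm <- smoothOutliers(pt$track)
    segs <- segmentCBS(sm, nPerm = 150, seed = 3)
    y <- S4Vectors::mcols(sm)$log10_ratio
    w <- S4Vectors::mcols(segs)$n_probes
    expect_equal(sum(w * S4Vectors::mcols(segs)$seg_mean) / sum(w),
        mean(y), tolerance = 1e-12)
    # segments partition the probe extent
    expect_equal(sum(w), length(sm))
})

test_that("gene scores average segmented probe values with min 3 probes", {
    # 5 probes: 3 in a segment at 0.2, 2 in a segment at -0.1
    tr <- flatTrack(c(0.2, 0.2, 0.2, -0.1, -0.1))
    segs <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(1, 3001), end = c(2060, 4060)),
        n_probes = c(3L, 2L), seg_mean = c(0.2, -0.1))
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(1, 1, 3001), end = c(4060, 2060, 4060)),
        name = c("span", "inA", "twoProbes"))
    out <- geneCopyNumber(segs, tr, genes)
    expect_equal(out$log10CN[out$gene == "span"],
        (3 * 0.2 + 2 * (-0.1)) / 5, tolerance = 1e-12)
    expect_equal(out$log10CN[out$gene == "inA"], 0.2)
    expect_false("twoProbes" %in% out$gene)   # < 3 probes dropped
})

test_that("genes off the track are dropped and probe order is irrelevant", {
    pt <- simulateProbeTrack(simConfig(nChroms = 1, nSegments = 0, seed = 2))
    segs <- segmentCBS(pt$track, nPerm = 100, seed = 1)
    genes <- GenomicRanges::GRanges(c("chr1", "chrX"),
        IRanges::IRanges(start = c(1, 1), end = c(30000, 30000)),
        name = c("onTrack", "offTrack"))
    expect_message(out <- geneCopyNumber(segs, pt$track, genes), "dropped")
    expect_equal(out$gene, "onTrack")
    shuffled <- pt$track[sample(length(pt$track))]
    out2 <- suppressMessages(geneCopyNumber(segs, shuffled, genes))
    expect_equal(out2, out)
})

test_that("met-specific recurrent CNA calls follow the definitional rules", {
    genes <- paste0("G", 1:5)
    cases <- paste0("c", 1:3)
    samples <- as.vector(outer(cases, c("P", "M"), paste0))
    cn <- matrix(0, 5, 6, dimnames = list(genes, samples))
    case <- rep(cases, 2); tissue <- rep(c("primary", "metastasis"), each = 3)
    # G1: amplified in mets of 2 cases, never in primaries
    cn["G1", c("c1M", "c2M")] <- 0.4
    # G2: amplified in met of 1 case only -> not recurrent
    cn["G2", "c1M"] <- 0.4
    # G3: lost in primaries of 2 cases -> primary-only loss
    cn["G3", c("c1P", "c3P")] <- -0.4
    set.seed(1)
    expr <- matrix(rnorm(30, 7, 0.01), 5, 6,
        dimnames = list(genes, samples))
    expr["G1", ] <- 7 + 2 * cn["G1", ]      # perfectly correlated
    expr["G3", ] <- 7 + 2 * cn["G3", ]
    out <- metSpecificCNAs(cn, case, tissue, expr)
    g1 <- out[out$gene == "G1", ]
    expect_equal(g1$direction, "amplified")
    expect_equal(g1$specificity, "met-only")
    expect_equal(g1$nCases, 2)
    expect_gt(g1$r, 0.7)
    expect_false("G2" %in% out$gene)
    g3 <- out[out$gene == "G3", ]
    expect_equal(g3$specificity, "primary-only")
    expect_equal(g3$direction, "lost")
    # without expression the call is kept but flagged uncorrelatable
    out2 <- metSpecificCNAs(cn, case, tissue, expr = NULL)
    expect_true(all(is.na(out2$r)))
    expect_true("G1" %in% out2$gene)
})

test_that("an engineered met-only amplicon is the unique end-to-end call", {
    # 3 cases x 2 tissues; chromosome of 60 probes; probes 21-35 amplified
    # only in the metastases of cases 1 and 2, driving expression
    set.seed(55)
    nP <- 60
    geneModels <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = seq(1, by = 5000, length.out = 12),
            width = 4500),
        name = sprintf("G%02d", 1:12))   # 5 probes per gene
    cases <- paste0("c", 1:3)
    cn <- NULL; expr <- NULL
    for (cs in cases) for (ts in c("primary", "metastasis")) {
        y <- rnorm(nP, 0, 0.03)
        if (ts == "metastasis" && cs %in% c("c1", "c2")) {
            y[21:35] <- y[21:35] + 0.45
        }
        tr <- flatTrack(y)
        segs <- segmentCBS(tr, nPerm = 100, seed = 7)
        g <- geneCopyNumber(segs, tr, geneModels)
        v <- setNames(rep(NA_real_, 12), sprintf("G%02d", 1:12))
        v[g$gene] <- g$log10CN
        cn <- cbind(cn, v)
        expr <- cbind(expr, 7 + 2 * v + rnorm(12, 0, 0.02))
    }
    lab <- expand.grid(tissue = c("primary", "metastasis"), case = cases)
    colnames(cn) <- colnames(expr) <- paste0(lab$case, "_", lab$tissue)
    out <- metSpecificCNAs(cn, as.character(lab$case),
        as.character(lab$tissue), expr, ampThresh = 0.1)
    expect_true(all(out$specificity == "met-only"))
    expect_true(all(out$direction == "amplified"))
    expect_setequal(unique(out$gene), c("G05", "G06", "G07"))
})

test_that("CNA profile clustering reports co-clustering pairs", {
    set.seed(18)
    nGenes <- 120; nCases <- 12
    backbone <- matrix(rnorm(nGenes * nCases, 0, 0.3), nGenes, nCases)
    cn <- matrix(0, nGenes, 2 * nCases)
    case <- rep(paste0("c", 1:nCases), each = 2)
    tissue <- rep(c("primary", "metastasis"), nCases)
    for (i in seq_len(nCases)) {
        for (j in 1:2) {
            cn[, 2 * (i - 1) + j] <- backbone[, i] + rnorm(nGenes, 0, 0.1)
        }
    }
    colnames(cn) <- paste0(case, "_", tissue)
    rownames(cn) <- paste0("g", seq_len(nGenes))
    res <- clusterCNAProfiles(cn, case, tissue)
    expect_gte(res$nCoClustered, 8L)
    # duplicated sample has distance 0 and merges first (a cherry)
    cn2 <- cn; cn2[, 2] <- cn2[, 1]
    res2 <- clusterCNAProfiles(cn2, case, tissue)
    expect_true(res2$pairs$coClustered[1])
    expect_equal(min(res2$dist), 0, tolerance = 1e-12)
    # sign-flipped profile sits at the maximum distance 2
    d3 <- 1 - cor(cbind(a = cn[, 1], b = -cn[, 1], c = cn[, 2]))
    expect_equal(d3["a", "b"], 2, tolerance = 1e-12)
    # zero-variance sample excluded with a warning
    cn4 <- cn; cn4[, 5] <- 1
    expect_warning(res4 <- clusterCNAProfiles(cn4, case, tissue),
        "zero-variance")
    expect_equal(res4$excluded, colnames(cn)[5])
})
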