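# median-vote scoring, Cox screening and signature selection

mkExpr <- function(nGenes, nPat, seed = 1) {
    set.seed(seed)
    matrix(rnorm(nGenes * nPat), nGenes, nPat,
        dimnames = list(paste0("g", seq_len(nGenes)),
            paste0("p", seq_len(nPat))))
}

test_that("vote scores match the brute-force oracle on random matrices", {
    sig <- metSignature(paste0("g", 1:6),
        directions = c("up", "up", "down", "up", "down", "up"))
    for (s in 1:25) {
        expr <- mkExpr(6, 3, seed = s)   # distinct values w.p. 1
        got <- scorePatients(expr, sig)
        want <- voteOracle(expr, signatureDirections(sig), 3L)
        expect_identical(got$score, as.integer(want$score))
        expect_identical(got$group, want$group)
    }
})

test_that("a patient sitting at every median scores 0 and is low risk", {
    # 3 patients, distinct values: the middle patient IS the median
    expr <- matrix(c(1, 2, 3), 6, 3, byrow = TRUE,
        dimnames = list(paste0("g", 1:6), paste0("p", 1:3)))
    sig <- metSignature(paste0("g", 1:6))
    got <- scorePatients(expr, sig)
    expect_equal(got$score[2], 0L)
    expect_equal(got$group[2], "low")
})

test_that("score > 3 of 6 points assigns the high-risk group", {
    # per-gene medians all equal patient 1's values (0); patient 3 exceeds
    # the median on exactly 4 of the 6 up-genes
    expr <- matrix(0, 6, 3,
        dimnames = list(paste0("g", 1:6), paste0("p", 1:3)))
    expr[, 2] <- c(-1, -1, -1, -1, 1, 1)
    expr[, 3] <- c(1, 1, 1, 1, -2, -2)
    sig <- metSignature(paste0("g", 1:6))
    got <- scorePatients(expr, sig)
    expect_equal(got$score[3], 4L)
    expect_equal(got$group[3], "high")
    expect_equal(got$score[1], 0L)       # the all-median patient
})

test_that("flipping all directions complements the score for non-medians", {
    sig <- metSignature(paste0("g", 1:6))
    flipped <- metSignature(paste0("g", 1:6), directions = "down")
    for (s in 1:10) {
        expr <- mkExpr(6, 3, seed = 100 + s)
        a <- scorePatients(expr, sig)$score
        b <- scorePatients(expr, flipped)$score
        med <- apply(expr, 1, median)
        nonMedian <- vapply(1:3, function(j) all(expr[, j] != med),
            logical(1))
        expect_equal(b[nonMedian], 6L - a[nonMedian])
    }
})

test_that("scoring is invariant to strictly monotone per-gene transforms", {
    expr <- mkExpr(6, 40, seed = 8)
    sig <- metSignature(paste0("g", 1:6),
        directions = rep(c("up", "down"), 3))
    base <- scorePatients(expr, sig)
    expect_identical(scorePatients(exp(expr), sig), base)
    expr2 <- expr * 3.7 + 12
    dimnames(expr2) <- dimnames(expr)
    expect_identical(scorePatients(expr2, sig), base)
})

test_that("patient permutation permutes assignments identically", {
    expr <- mkExpr(6, 20, seed = 4)
    sig <- metSignature(paste0("g", 1:6))
    base <- scorePatients(expr, sig)
    perm <- sample(20)
    got <- scorePatients(expr[, perm], sig)
    expect_identical(got$score, base$score[perm])
})

test_that("scoring rejects missing genes and single-patient cohorts", {
    expr <- mkExpr(3, 5)
    expect_error(scorePatients(expr, metSignature(c("g1", "gX", "gY"))),
        "gX, gY")
    expect_error(
        scorePatients(expr[, 1, drop = FALSE], metSignature(c("g1", "g2"))),
        "2 patients")
})

test_that("Cox screen is calibrated under the null and errors sensibly", {
    set.seed(12)
    n <- 120
    expr <- mkExpr(150, n, seed = 12)
    time <- rexp(n, 0.05)
    event <- rbinom(n, 1, 0.8)
    res <- coxScreen(expr, time, event)
    expect_equal(nrow(res), 150L)
    expect_lt(mean(res$significant), 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
    ks <- suppressWarnings(ks.test(res$p[res$converged], "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_error(coxScreen(expr, time, rep(0, n)), "10 events")
})

test_that("signature selection returns k candidates unchanged when exact", {
    sig <- metSignature(paste0("g", 1:6))
    sc <- simulateSurvivalCohort(
        simConfig(nPatients = 500, logHrPerPoint = 0.8, seed = 31), sig)
    ds <- list(list(expr = sc$expr, time = sc$clinical$time,
        event = sc$clinical$event))
    cand <- data.frame(gene = paste0("g", 1:6), direction = "up")
    out <- suppressWarnings(selectSignature(cand, ds, k = 6))
    expect_setequal(signatureGenes(out), cand$gene)
})

test_that("selection recovers planted signal genes among decoys", {
    planted <- sprintf("sig%02d", 1:6)
    sig <- metSignature(planted)
    decoys <- sprintf("dec%02d", 1:6)
    sc <- simulateSurvivalCohort(
        simConfig(nPatients = 500, logHrPerPoint = 0.8, seed = 17), sig,
        nNullGenes = decoys)
    ds <- list(list(expr = sc$expr, time = sc$clinical$time,
        event = sc$clinical$event))
    cand <- data.frame(gene = c(planted, decoys), direction = "up")
    out <- selectSignature(cand, ds, k = 6)
    expect_gte(length(intersect(signatureGenes(out), planted)), 5L)
})
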