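# Independent brute-force oracles used to verify the package's
# implementations. These deliberately share no code with R/.

# Benjamini-Hochberg step-up, written out explicitly
bhOracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        val <- min(prev, p[ord[i]] * m / i)
        q[ord[i]] <- val
        prev <- val
    }
    q
}

# product-limit estimator by explicit looping over distinct times
kmOracle <- function(time, event) {
    ts <- sort(unique(time[event == 1]))
    s <- 1
    surv <- numeric(length(ts))
    for (i in seq_along(ts)) {
        nRisk <- sum(time >= ts[i])
        d <- sum(time == ts[i] & event == 1)
        s <- s * (1 - d / nRisk)
        surv[i] <- s
    }
    list(time = ts, surv = surv,
        median = if (any(surv <= 0.5)) ts[min(which(surv <= 0.5))] else NA)
}

# two-group log-rank via explicit 2x2 tables at each distinct event time
logrankOracle <- function(time, event, group1) {
    ts <- sort(unique(time[event == 1]))
    O <- E <- V <- 0
    for (t in ts) {
        n <- sum(time >= t)
        n1 <- sum(time >= t & group1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & group1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1) {
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
        }
    }
    chisq <- if (V > 0) (O - E)^2 / V else 0
    list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# median-vote scorer by explicit per-patient loops
voteOracle <- function(expr, directions, threshold) {
    med <- apply(expr, 1, median)
    score <- integer(ncol(expr))
    for (j in seq_len(ncol(expr))) {
        s <- 0
        for (g in rownames(expr)) {
            if (directions[g] == "up" && expr[g, j] > med[g]) s <- s + 1
            if (directions[g] == "down" && expr[g, j] < med[g]) s <- s + 1
        }
        score[j] <- s
    }
    list(score = score, group = ifelse(score > threshold, "high", "low"))
}

# a small deterministic paired cohort built by hand; case ids match the
# staining generator's ("case01", ...) so the two can be joined
toyCohort <- function(nGenes = 10, nCases = 4, seed = 99) {
    set.seed(seed)
    m <- matrix(rnorm(nGenes * 2 * nCases, mean = 7), nGenes, 2 * nCases)
    rownames(m) <- paste0("g", seq_len(nGenes))
    colnames(m) <- paste0("s", seq_len(2 * nCases))
    pairedCohort(m,
        case = rep(sprintf("case%02d", seq_len(nCases)), each = 2),
        tissue = rep(c("primary", "metastasis"), nCases))
}
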