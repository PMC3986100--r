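# Kaplan-Meier, log-rank, and signature evaluation across strata

test_that("product-limit estimate matches hand computation", {
    km <- kmFit(c(1, 2, 3, 4), c(1, 1, 1, 1))
    expect_equal(km@surv, c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)
    expect_equal(km@median, 2)
})

test_that("an all-censored cohort yields a flat curve, median not reached", {
    km <- kmFit(c(2, 5, 7), c(0, 0, 0))
    expect_true(all(km@surv == 1))
    expect_true(is.na(km@median))
})

test_that("KM matches a brute-force oracle under random censoring", {
    set.seed(30)
    for (rep in 1:40) {
        n <- sample(3:20, 1)
        time <- round(rexp(n, 0.2), 2) + 0.01
        event <- rbinom(n, 1, 0.7)
        if (sum(event) == 0) event[1] <- 1
        km <- kmFit(time, event)
        orc <- kmOracle(time, event)
        atEvents <- km@surv[match(orc$time, km@time)]
        expect_equal(atEvents, orc$surv, tolerance = 1e-12)
        expect_equal(km@median, orc$median)
    }
})

test_that("KM median approaches ln2/lambda for exponential data", {
    # a single n = 1000 median has ~4.6% relative SE, so average a few
    # replicates to make the 5% closed-form check stable
    set.seed(77)
    lam <- 0.1
    meds <- vapply(1:5, function(i) kmFit(rexp(1000, lam), rep(1, 1000))@median,
        numeric(1))
    expect_lt(abs(mean(meds) - log(2) / lam) / (log(2) / lam), 0.05)
})

test_that("log-rank matches the 2x2-table oracle and survdiff", {
    time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
    grp <- c(TRUE, TRUE, FALSE, FALSE)
    lr <- logrankTest(time, event, grp)
    orc <- logrankOracle(time, event, grp)
    expect_equal(unname(lr$statistic), orc$chisq, tolerance = 1e-12)
    expect_equal(lr$p.value, orc$p, tolerance = 1e-12)
    # larger example with censoring and ties
    set.seed(5)
    t2 <- c(1, 1, 2, 3, 5, 5, 6, 8); e2 <- c(1, 0, 1, 1, 1, 1, 0, 1)
    g2 <- rep(c(TRUE, FALSE), 4)
    lr2 <- logrankTest(t2, e2, g2)
    orc2 <- logrankOracle(t2, e2, g2)
    expect_equal(unname(lr2$statistic), orc2$chisq, tolerance = 1e-12)
    sd2 <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
    expect_equal(unname(lr2$statistic), sd2$chisq, tolerance = 1e-10)
})

test_that("identical groups give statistic 0 and p = 1", {
    time <- rep(c(1, 3, 7, 9), 2)
    event <- rep(c(1, 1, 0, 1), 2)
    grp <- rep(c(TRUE, FALSE), each = 4)
    lr <- logrankTest(time, event, grp)
    expect_equal(unname(lr$statistic), 0)
    expect_equal(lr$p.value, 1)
})

test_that("log-rank is symmetric in group labels and calibrated", {
    set.seed(9)
    time <- rexp(60, 0.1); event <- rbinom(60, 1, 0.8)
    grp <- rep(c(TRUE, FALSE), 30)
    expect_equal(logrankTest(time, event, grp)$statistic,
        logrankTest(time, event, !grp)$statistic, tolerance = 1e-12)
    pvals <- vapply(1:300, function(i) {
        t <- rexp(40, 0.1); e <- rbinom(40, 1, 0.8)
        if (sum(e) == 0) e[1] <- 1
        logrankTest(t, e, rep(c(TRUE, FALSE), 20))$p.value
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("binary-covariate Cox score test agrees with log-rank", {
    set.seed(41)
    time <- rexp(200, 0.1 * exp(0.5 * rep(0:1, 100)))
    event <- rbinom(200, 1, 0.85)
    grp <- rep(c(FALSE, TRUE), 100)
    lr <- logrankTest(time, event, grp)
    cx <- survival::coxph(survival::Surv(time, event) ~ grp)
    pScore <- pchisq(cx$score, 1, lower.tail = FALSE)
    expect_equal(lr$p.value, pScore, tolerance = 1e-6)
})

test_that("signature evaluation separates a planted effect", {
    sig <- metSignature(paste0("g", 1:6))
    sc <- simulateSurvivalCohort(
        simConfig(nPatients = 400, logHrPerPoint = 0.4, seed = 23), sig)
    ds <- list(tcga = list(expr = sc$expr, clinical = sc$clinical))
    res <- evaluateSignature(ds, sig, endpoint = "OS", strata = "all")
    expect_lt(res$logrankP, 0.05)
    expect_lt(res$medianHigh, res$medianLow)
})

test_that("stratum-specific effects are detected only where planted", {
    set.seed(61)
    n <- 600
    expr <- matrix(rnorm(6 * n), 6, n,
        dimnames = list(paste0("g", 1:6), paste0("p", 1:n)))
    sig <- metSignature(paste0("g", 1:6))
    score <- scorePatients(expr, sig)$score
    residual <- rep(c("none", "macro"), n / 2)
    # hazard depends on score only in the no-residual stratum
    lhr <- ifelse(residual == "none", 0.5, 0)
    time <- rexp(n, 0.02 * exp(lhr * score))
    clin <- data.frame(patient = colnames(expr), time = time,
        event = 1L, treated = TRUE, residual_disease = residual)
    res <- evaluateSignature(list(d = list(expr = expr, clinical = clin)),
        sig, strata = c("no-residual", "residual"))
    expect_lt(res$logrankP[res$stratum == "no-residual"], 0.05)
    expect_gt(res$logrankP[res$stratum == "residual"], 0.05)
})

test_that("PFS endpoint equal to OS reproduces OS results", {
    sig <- metSignature(paste0("g", 1:6))
    sc <- simulateSurvivalCohort(
        simConfig(nPatients = 150, seed = 13), sig)
    clin <- sc$clinical
    clin$pfs_time <- clin$time
    clin$pfs_event <- clin$event
    ds <- list(d = list(expr = sc$expr, clinical = clin))
    os <- evaluateSignature(ds, sig, endpoint = "OS")
    pfs <- evaluateSignature(ds, sig, endpoint = "PFS")
    expect_equal(pfs$logrankP, os$logrankP)
    expect_equal(pfs$medianHigh, os$medianHigh)
})

test_that("tiny strata are skipped with a warning", {
    sig <- metSignature(c("g1", "g2"), threshold = 1)
    set.seed(3)
    expr <- matrix(rnorm(2 * 30), 2, 30,
        dimnames = list(c("g1", "g2"), paste0("p", 1:30)))
    clin <- data.frame(patient = colnames(expr),
        time = rexp(30, 0.1), event = 1L,
        residual_disease = c(rep("none", 29), "macro"))
    expect_warning(
        expect_error(
            evaluateSignature(list(d = list(expr = expr, clinical = clin)),
                sig, strata = "residual"),
            "no stratum"),
        "skipped")
})
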