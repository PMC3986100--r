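# Kaplan-Meier / log-rank machinery. KM estimation goes through
# survival::survfit; the two-group log-rank statistic is computed natively
# (vectorized hypergeometric sums) because the empirical-null loop evaluates
# it tens of thousands of times per run.

#' Kaplan-Meier fit with median survival CI
#'
#' Product-limit estimator S(t) = prod_{t_j <= t} (1 - d_j / n_j) with
#' Greenwood variance; the median is the smallest time with S(t) <= 0.5 and
#' its 95% CI comes from inverting log-log transformed pointwise bands
#' (Brookmeyer-Crowley style, \code{conf.type = "log-log"}).  Censored
#' observations tied with events are counted at risk at that time
#' (censored-after-events convention).
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param confLevel Confidence level for the median CI.
#' @return A [KMCurve-class].  With zero events the curve is flat at 1 and
#'   the median is reported as not reached (\code{NA}).
#' @examples
#' kmFit(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' @export
kmFit <- function(time, event, confLevel = 0.95) {
    stopifnot(length(time) == length(event), all(time > 0),
        all(event %in% c(0, 1)))
    fit <- survfit(Surv(time, event) ~ 1, conf.type = "log-log",
        conf.int = confLevel)
    tab <- summary(fit)$table
    # median by the definitional rule: smallest t with S(t) <= 0.5
    # (survfit averages the two flanking times when S hits 0.5 exactly)
    med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else
        NA_real_
    new("KMCurve",
        time = fit$time, surv = fit$surv,
        nRisk = fit$n.risk, nEvent = fit$n.event,
        n = as.integer(length(time)), nEvents = as.integer(sum(event)),
        median = med,
        medianCI = unname(c(tab[sprintf("%gLCL", confLevel)],
            tab[sprintf("%gUCL", confLevel)])))
}

# Precompute the group-independent parts of the log-rank statistic: sorted
# order, distinct-time blocks, per-block event totals and risk-set sizes.
.logrankPrep <- function(time, event) {
    ord <- order(time)
    timeS <- time[ord]
    eventS <- as.numeric(event[ord])
    newBlock <- !duplicated(timeS)
    bid <- cumsum(newBlock)
    n <- length(timeS)
    firstIdx <- which(newBlock)
    nRisk <- n - firstIdx + 1
    dTot <- as.vector(rowsum(eventS, bid))
    list(ord = ord, eventS = eventS, bid = bid, nBlocks = max(bid),
        nRisk = nRisk, dTot = dTot, n = n)
}

# Log-rank chi-square given a precomputed prep and a logical group vector
# (in original observation order). Returns c(chisq, p, O1, E1).
.logrankFromPrep <- function(prep, group) {
    g <- as.numeric(group[prep$ord])
    perBlock <- rowsum(cbind(g, prep$eventS * g), prep$bid)
    leave1 <- perBlock[, 1L]
    d1 <- perBlock[, 2L]
    n1 <- sum(g) - c(0, cumsum(leave1))[seq_len(prep$nBlocks)]
    dT <- prep$dTot
    nR <- prep$nRisk
    keep <- dT > 0
    E1 <- sum(dT[keep] * n1[keep] / nR[keep])
    vKeep <- keep & nR > 1
    V <- sum(dT[vKeep] * (n1[vKeep] / nR[vKeep]) *
        (1 - n1[vKeep] / nR[vKeep]) * (nR[vKeep] - dT[vKeep]) /
        (nR[vKeep] - 1))
    O1 <- sum(d1[keep])
    chisq <- if (V > 0) (O1 - E1)^2 / V else 0
    c(chisq = chisq, p = pchisq(chisq, df = 1L, lower.tail = FALSE),
        O1 = O1, E1 = E1)
}

#' Two-group log-rank test
#'
#' At every distinct event time, compares the observed events in the first
#' group with the hypergeometric expectation given the risk sets, and sums
#' observed-minus-expected over times; the squared sum over the summed
#' hypergeometric variance is chi-square with 1 df under the null of equal
#' hazards.  Symmetric in the group labels.
#'
#' @param time,event Survival data for all patients.
#' @param group Logical or two-level factor splitting the patients.
#' @return An object of class \code{"htest"} with \code{statistic},
#'   \code{p.value}, and observed/expected event counts in \code{estimate}.
#' @examples
#' logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
logrankTest <- function(time, event, group) {
    stopifnot(length(time) == length(event), length(group) == length(time))
    if (is.factor(group) || is.character(group)) {
        lv <- unique(as.character(group))
        if (length(lv) != 2L) stop("'group' must have exactly two levels")
        group <- as.character(group) == lv[1L]
    }
    group <- as.logical(group)
    if (!any(group) || all(group)) stop("both groups must be non-empty")
    if (sum(event[group]) + sum(event[!group]) == 0) {
        stop("log-rank test requires at least one event")
    }
    r <- .logrankFromPrep(.logrankPrep(time, event), group)
    structure(list(
        statistic = c("chi-square" = unname(r["chisq"])),
        parameter = c(df = 1L),
        p.value = unname(r["p"]),
        estimate = c("observed (group 1)" = unname(r["O1"]),
            "expected (group 1)" = unname(r["E1"])),
        method = "Two-group log-rank test",
        data.name = sprintf("%d vs %d patients", sum(group), sum(!group))
    ), class = "htest")
}

#' Evaluate a signature across survival datasets and strata
#'
#' Applies the published evaluation order: restrict to treated patients
#' (column \code{treated}, if present), compute median-vote risk groups on
#' the treated cohort (cutpoints from this filtered cohort), then examine
#' residual-disease strata \emph{after} scoring, fitting Kaplan-Meier
#' curves per risk group and the high-vs-low log-rank test for the chosen
#' endpoint.
#'
#' @param datasets Named list; each element a list with \code{expr} (gene x
#'   patient matrix) and \code{clinical} (data.frame with \code{time},
#'   \code{event}; for PFS, \code{pfs_time}/\code{pfs_event}; optional
#'   \code{treated} logical and \code{residual_disease} in
#'   \code{c("none", "macro")}).
#' @param signature A [MetSignature-class].
#' @param endpoint \code{"OS"} or \code{"PFS"}.
#' @param strata Subset of \code{c("all", "no-residual", "residual")}.
#' @return data.frame with one row per dataset x stratum: group sizes,
#'   median survival with CI bounds per group, and the log-rank p.  Strata
#'   with fewer than 2 patients in either risk group are skipped with a
#'   warning.
#' @export
evaluateSignature <- function(datasets, signature, endpoint = c("OS", "PFS"),
                              strata = "all") {
    endpoint <- match.arg(endpoint)
    stopifnot(length(datasets) >= 1L,
        all(strata %in% c("all", "no-residual", "residual")))
    if (is.null(names(datasets))) {
        names(datasets) <- paste0("dataset", seq_along(datasets))
    }
    out <- list()
    for (nm in names(datasets)) {
        ds <- datasets[[nm]]
        clin <- ds$clinical
        expr <- ds$expr
        if ("treated" %in% colnames(clin)) {
            keep <- as.logical(clin$treated)
            clin <- clin[keep, , drop = FALSE]
            expr <- expr[, keep, drop = FALSE]
        }
        risk <- scorePatients(expr, signature)
        tm <- if (endpoint == "OS") clin$time else clin$pfs_time
        ev <- if (endpoint == "OS") clin$event else clin$pfs_event
        if (is.null(tm) || is.null(ev)) {
            stop("dataset '", nm, "' lacks ", endpoint, " columns")
        }
        for (st in strata) {
            sel <- switch(st,
                "all" = rep(TRUE, nrow(clin)),
                "no-residual" = clin$residual_disease == "none",
                "residual" = clin$residual_disease == "macro")
            hi <- risk$group[sel] == "high"
            if (sum(hi) < 2L || sum(!hi) < 2L) {
                warning("stratum '", st, "' in dataset '", nm,
                    "' has < 2 patients in a risk group; skipped")
                next
            }
            kmH <- kmFit(tm[sel][hi], ev[sel][hi])
            kmL <- kmFit(tm[sel][!hi], ev[sel][!hi])
            lr <- logrankTest(tm[sel], ev[sel], hi)
            out[[length(out) + 1L]] <- data.frame(
                dataset = nm, stratum = st, endpoint = endpoint,
                nHigh = sum(hi), nLow = sum(!hi),
                medianHigh = kmH@median,
                medianHighLCL = kmH@medianCI[1], medianHighUCL = kmH@medianCI[2],
                medianLow = kmL@median,
                medianLowLCL = kmL@medianCI[1], medianLowUCL = kmL@medianCI[2],
                logrankP = lr$p.value,
                stringsAsFactors = FALSE
            )
        }
    }
    if (!length(out)) {
        stop("no stratum could be evaluated")
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
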