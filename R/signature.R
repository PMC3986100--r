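#' Median-vote risk scoring of patients
#'
#' The vote score of the metastatic signature: for every signature gene the
#' cutpoint is the median expression across the patients of \emph{this}
#' cohort (cutpoints are never transferred between cohorts).  A patient
#' gains one point per up-in-metastasis gene with expression strictly above
#' its median and per down gene strictly below its median; ties at the
#' median score nothing.  Patients with total score strictly greater than
#' the signature threshold form the high-risk group (at k = 6 and
#' threshold 3 this is the "> 3 points" rule).
#'
#' Because the score only compares each value with a per-gene order
#' statistic, it is invariant to any strictly monotone per-gene transform
#' of the expression values.
#'
#' @param expr Numeric gene x patient matrix (log2 scale; any monotone
#'   transform gives identical scores).
#' @param signature A [MetSignature-class].
#' @return data.frame: patient, score (integer in [0, k]), group
#'   (\code{"high"}/\code{"low"}).
#' @examples
#' expr <- matrix(rnorm(6 * 20), 6, 20,
#'     dimnames = list(paste0("g", 1:6), paste0("p", 1:20)))
#' sig <- metSignature(paste0("g", 1:6))
#' table(scorePatients(expr, sig)$group)
#' @export
scorePatients <- function(expr, signature) {
    stopifnot(is.matrix(expr), is(signature, "MetSignature"))
    genes <- signatureGenes(signature)
    missing <- setdiff(genes, rownames(expr))
    if (length(missing)) {
        stop("signature genes absent from expression matrix: ",
            paste(missing, collapse = ", "))
    }
    if (ncol(expr) < 2L) {
        stop("scoring needs >= 2 patients (cohort median is degenerate)")
    }
    sub <- expr[genes, , drop = FALSE]
    med <- apply(sub, 1L, median)
    up <- signatureDirections(signature) == "up"
    pts <- (sub > med) * up + (sub < med) * (!up)
    score <- as.integer(colSums(pts))
    data.frame(
        patient = colnames(expr),
        score = score,
        group = ifelse(score > riskThreshold(signature), "high", "low"),
        stringsAsFactors = FALSE,
        row.names = NULL
    )
}

#' Univariate Cox proportional-hazards screen
#'
#' Fits one Cox model per gene with continuous expression as the only
#' covariate (partial likelihood, Efron handling of ties) and reports the
#' Wald test of the coefficient.  Non-converging or monotone-likelihood
#' fits are flagged and their p left \code{NA}.
#'
#' @param expr Gene x patient numeric matrix.
#' @param time,event Survival times and event indicators (1 = event),
#'   aligned to the columns of \code{expr}.
#' @param genes Genes to screen (default: all rows).
#' @param alpha Significance level for the \code{significant} flag.
#' @return data.frame: gene, coef, se, z, p, significant, converged.
#' @examples
#' sig <- metSignature(paste0("g", 1:3), threshold = 1)
#' sc <- simulateSurvivalCohort(simConfig(nPatients = 120, seed = 4), sig)
#' coxScreen(sc$expr, sc$clinical$time, sc$clinical$event)
#' @export
coxScreen <- function(expr, time, event, genes = rownames(expr),
                      alpha = 0.05) {
    stopifnot(is.matrix(expr), length(time) == ncol(expr),
        length(event) == ncol(expr))
    if (sum(event) < 10L) {
        stop("Cox screen requires >= 10 events (got ", sum(event), ")")
    }
    missing <- setdiff(genes, rownames(expr))
    if (length(missing)) {
        stop("genes absent from expression matrix: ",
            paste(missing, collapse = ", "))
    }
    srv <- Surv(time, event)
    rows <- lapply(genes, function(g) {
        xg <- expr[g, ]
        conv <- TRUE
        fit <- withCallingHandlers(
            tryCatch(coxph(srv ~ xg, ties = "efron"), error = function(e) NULL),
            warning = function(w) {
                conv <<- FALSE
                invokeRestart("muffleWarning")
            }
        )
        if (is.null(fit)) {
            return(data.frame(gene = g, coef = NA_real_, se = NA_real_,
                z = NA_real_, p = NA_real_, converged = FALSE))
        }
        s <- summary(fit)$coefficients
        data.frame(gene = g, coef = s[1, "coef"], se = s[1, "se(coef)"],
            z = s[1, "z"], p = s[1, "Pr(>|z|)"], converged = conv)
    })
    res <- do.call(rbind, rows)
    res$p[!res$converged] <- NA_real_
    res$significant <- !is.na(res$p) & res$p < alpha
    rownames(res) <- NULL
    if (any(!res$converged)) {
        message("coxScreen: ", sum(!res$converged),
            " gene(s) flagged non-converged/monotone and excluded")
    }
    res
}

# max log-rank p of the high/low split across datasets; degenerate splits
# (all patients in one group) count as p = 1
.subsetObjective <- function(genes, directions, datasets, threshold) {
    sig <- metSignature(genes, directions[genes], threshold = threshold)
    worst <- 0
    for (ds in datasets) {
        risk <- scorePatients(ds$expr, sig)
        hi <- risk$group == "high"
        p <- if (!any(hi) || all(hi)) 1 else {
            logrankTest(ds$time, ds$event, hi)$p.value
        }
        worst <- max(worst, p)
    }
    worst
}

#' Derive a k-gene signature from differential-expression candidates
#'
#' Reconstructs the two-stage selection: candidate genes are first screened
#' by univariate Cox regression in the training (first) dataset; the
#' retained genes are then searched for the size-k subset whose median-vote
#' high/low split has the smallest \emph{worst-case} (maximum) log-rank p
#' across all supplied datasets.  The search is exhaustive while
#' \code{choose(n, k) <= searchCap}, otherwise greedy forward selection;
#' both iterate genes in lexicographic order, which is the documented
#' tie-break.
#'
#' @param candidates data.frame with columns \code{gene} and
#'   \code{direction} (as returned by [candidateList()]).
#' @param datasets Non-empty list; each element a list with \code{expr}
#'   (gene x patient matrix), \code{time} and \code{event}.  The first
#'   element is the training set for the Cox screen.
#' @param k Signature size (default 6).
#' @param threshold High-risk point threshold (default \code{floor(k/2)}).
#' @param alphaScreen Cox screen significance level.
#' @param searchCap Maximum number of subsets for exhaustive search.
#' @return A [MetSignature-class].  If fewer than k genes survive the
#'   screen, all survivors are returned with a warning.
#' @export
selectSignature <- function(candidates, datasets, k = 6,
                            threshold = floor(k / 2),
                            alphaScreen = 0.05, searchCap = 5000) {
    stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L,
        all(c("gene", "direction") %in% colnames(candidates)),
        length(datasets) >= 1L)
    directions <- setNames(candidates$direction, candidates$gene)
    train <- datasets[[1L]]
    screen <- coxScreen(train$expr, train$time, train$event,
        genes = candidates$gene, alpha = alphaScreen)
    retained <- sort(screen$gene[screen$significant])
    if (length(retained) == 0L) {
        stop("no candidate gene passes the Cox screen at alpha = ", alphaScreen)
    }
    if (length(retained) < k) {
        warning("only ", length(retained), " genes pass the Cox screen; ",
            "returning all of them")
        return(metSignature(retained, directions[retained],
            threshold = min(threshold, length(retained) - 1L)))
    }
    if (choose(length(retained), k) <= searchCap) {
        subs <- combn(retained, k, simplify = FALSE)
        objs <- vapply(subs, .subsetObjective, numeric(1),
            directions = directions, datasets = datasets,
            threshold = threshold)
        best <- subs[[which.min(objs)]]
    } else {
        best <- character()
        pool <- retained
        while (length(best) < k) {
            objs <- vapply(pool, function(g) {
                cur <- sort(c(best, g))
                .subsetObjective(cur, directions, datasets,
                    threshold = floor(length(cur) / 2))
            }, numeric(1))
            pick <- pool[which.min(objs)]
            best <- sort(c(best, pick))
            pool <- setdiff(pool, pick)
        }
    }
    metSignature(best, directions[best], threshold = threshold)
}
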