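#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order on a fully synthetic
#' cohort generated from \code{config}: \code{simulate} (write the
#' expression/sample-map/clinical/probe inputs plus ground truth),
#' \code{de} (quantile normalization, low-signal filter, paired
#' differential expression, candidate list), \code{derive} (Cox screen and
#' subset search for the k-gene signature across two simulated survival
#' datasets whose hazard follows the top candidates), \code{score} (risk
#' assignment on the first survival dataset), \code{survival}
#' (Kaplan-Meier / log-rank evaluation per stratum), \code{null} (random
#' gene-set empirical null), \code{cnv} (smoothing, CBS segmentation,
#' gene-level copy number) and \code{phenotype} (paired staining test and
#' Ki-67-delta gene correlation).  Every run writes its artifacts plus a
#' JSON manifest (file MD5 hashes, resolved parameters, seed, package
#' version) into \code{outDir}; reruns with an identical config reproduce
#' identical files.
#'
#' @param config A [SimConfig-class]; its seed governs every stage.
#' @param outDir Output directory (created if missing).
#' @param stages Character subset of the stage names above.
#' @param k,nRandom,nPerm Signature size, empirical-null set count and CBS
#'   permutation count (reduced defaults keep a full run interactive).
#' @return Invisibly, a list with the in-memory results of each executed
#'   stage and the manifest.
#' @examples
#' \donttest{
#' res <- runPipeline(simConfig(nGenes = 300, nPatients = 150, seed = 1),
#'     outDir = tempfile(), stages = c("simulate", "de"))
#' }
#' @export
runPipeline <- function(config = simConfig(), outDir = "metsig_run",
                        stages = c("simulate", "de", "derive", "score",
                            "survival", "null", "cnv", "phenotype"),
                        k = 6, nRandom = 500, nPerm = 200) {
    allStages <- c("simulate", "de", "derive", "score", "survival", "null",
        "cnv", "phenotype")
    bad <- setdiff(stages, allStages)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    stopifnot(is(config, "SimConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(...) file.path(outDir, ...)
    results <- list()
    written <- character()

    # --- simulate (always computed in memory; written only if requested)
    sim <- simulatePairedCohort(config)
    if ("simulate" %in% stages) {
        writePairedCohort(sim$cohort, pth("expression.tsv"),
            pth("sample_map.tsv"))
        jsonlite::write_json(as.list(sim$truth), pth("truth.json"),
            auto_unbox = TRUE)
        written <- c(written, pth("expression.tsv"), pth("sample_map.tsv"),
            pth("truth.json"))
        results$simulate <- sim
    }

    # --- de
    needDE <- any(c("de", "derive", "score", "survival", "null",
        "phenotype") %in% stages)
    if (needDE) {
        norm <- filterLowSignal(quantileNormalize(sim$cohort))
        de <- pairedDE(norm)
        cand <- suppressWarnings(candidateList(de))
        if ("de" %in% stages) {
            .writeTSV(de, pth("de_results.tsv"))
            .writeTSV(cand, pth("candidates.tsv"))
            written <- c(written, pth("de_results.tsv"), pth("candidates.tsv"))
            results$de <- list(de = de, candidates = cand)
        }
    }

    # --- survival datasets shared by derive / score / survival / null
    needSurv <- any(c("derive", "score", "survival", "null") %in% stages)
    if (needSurv) {
        if (nrow(cand) < k) {
            stop("only ", nrow(cand), " differential candidates; cannot ",
                "derive a k = ", k, " signature")
        }
        trueSig <- metSignature(cand$gene[seq_len(k)],
            cand$direction[seq_len(k)])
        otherGenes <- setdiff(cand$gene, signatureGenes(trueSig))
        mkDataset <- function(offset) {
            cfgI <- config
            cfgI@seed <- .streamSeed(config@seed, 100L + offset)
            sc <- simulateSurvivalCohort(cfgI, trueSig,
                nNullGenes = otherGenes)
            list(expr = sc$expr, clinical = sc$clinical,
                time = sc$clinical$time, event = sc$clinical$event)
        }
        datasets <- list(training = mkDataset(1L), validation = mkDataset(2L))
        writeClinicalTable(datasets$training$clinical, pth("clinical.tsv"))
        written <- c(written, pth("clinical.tsv"))
    }

    if ("derive" %in% stages) {
        sig <- selectSignature(cand, datasets, k = k)
        writeSignatureJSON(sig, pth("signature.json"))
        written <- c(written, pth("signature.json"))
        results$derive <- sig
    } else if (needSurv) {
        sig <- trueSig
    }

    if ("score" %in% stages) {
        risk <- scorePatients(datasets$training$expr, sig)
        .writeTSV(risk, pth("risk.tsv"))
        written <- c(written, pth("risk.tsv"))
        results$score <- risk
    }

    if ("survival" %in% stages) {
        ev <- evaluateSignature(datasets, sig, endpoint = "OS",
            strata = c("all", "no-residual", "residual"))
        .writeTSV(ev, pth("survival_results.tsv"))
        written <- c(written, pth("survival_results.tsv"))
        results$survival <- ev
    }

    if ("null" %in% stages) {
        tr <- datasets$training
        nullRes <- empiricalNull(tr$expr, tr$time, tr$event, sig,
            nRandom = nRandom, seed = .streamSeed(config@seed, 200L))
        jsonlite::write_json(list(
            observed_p = nullRes@observedP, n_random = nullRes@nRandom,
            n_lower = nullRes@nLower, empirical_p = nullRes@empiricalP,
            mode = nullRes@mode, seed = nullRes@seed),
            pth("empirical_null.json"), auto_unbox = TRUE, digits = NA)
        .writeTSV(data.frame(p = nullRes@randomP), pth("random_p.tsv"))
        written <- c(written, pth("empirical_null.json"), pth("random_p.tsv"))
        results$null <- nullRes
    }

    if ("cnv" %in% stages) {
        pt <- simulateProbeTrack(config)
        writeProbeTrack(pt$track, pth("probes.tsv"))
        sm <- smoothOutliers(pt$track)
        segs <- segmentCBS(sm, nPerm = max(100, nPerm),
            seed = .streamSeed(config@seed, 300L))
        writeSegTable(segs, "synthetic", pth("segments.seg"))
        geneModels <- .tileGenes(pt$track, probesPerGene = 10L)
        gcn <- geneCopyNumber(segs, sm, geneModels)
        .writeTSV(gcn, pth("gene_copy_number.tsv"))
        written <- c(written, pth("probes.tsv"), pth("segments.seg"),
            pth("gene_copy_number.tsv"))
        results$cnv <- list(segments = segs, genes = gcn)
    }

    if ("phenotype" %in% stages) {
        tab <- simulateStainingTable(nCases = config@nCases, effect = 1.5,
            seed = config@seed)
        writeStainingTable(tab, pth("staining.tsv"))
        plt <- pairedLogTest(tab)
        jsonlite::write_json(plt, pth("staining_test.json"),
            auto_unbox = TRUE, digits = NA)
        kc <- ki67CorrelatedGenes(sim$cohort, tab,
            topN = min(250, nrow(sim$cohort)))
        .writeTSV(kc, pth("ki67_correlated_genes.tsv"))
        written <- c(written, pth("staining.tsv"), pth("staining_test.json"),
            pth("ki67_correlated_genes.tsv"))
        results$phenotype <- list(stainingTest = plt, ki67Genes = kc)
    }

    manifest <- list(
        package = "metsig",
        version = as.character(utils::packageVersion("metsig")),
        r_version = as.character(getRversion()),
        seed = config@seed,
        stages = stages,
        parameters = list(k = k, nRandom = nRandom, nPerm = nPerm,
            config = .configAsList(config)),
        files = as.list(setNames(unname(md5sum(written)), basename(written)))
    )
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
        pretty = TRUE)
    jsonlite::write_json(.configAsList(config), pth("config.json"),
        auto_unbox = TRUE, pretty = TRUE)
    results$manifest <- manifest
    invisible(results)
}

.configAsList <- function(cfg) {
    nm <- slotNames(cfg)
    setNames(lapply(nm, function(s) slot(cfg, s)), nm)
}

# synthetic gene models tiling a probe track: consecutive runs of
# 'probesPerGene' probes become one gene
.tileGenes <- function(track, probesPerGene = 10L) {
    chrom <- as.character(seqnames(track))
    out <- list()
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        grp <- (seq_along(idx) - 1L) %/% probesPerGene
        for (g in unique(grp)) {
            probes <- idx[grp == g]
            out[[length(out) + 1L]] <- data.frame(
                chrom = ch,
                start = min(GenomicRanges::start(track)[probes]),
                end = max(GenomicRanges::end(track)[probes]),
                name = sprintf("%s_gene%03d", ch, g + 1L))
        }
    }
    df <- do.call(rbind, out)
    GRanges(df$chrom, IRanges(df$start, df$end), name = df$name)
}
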