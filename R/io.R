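# Readers and writers for the pipeline's plain-text formats. TSV is the
# lingua franca: tab-separated, header row, UTF-8, '.' decimal. Probe files
# are 0-based half-open (BED-like); GRanges objects in memory are 1-based.

.readTSV <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
        stringsAsFactors = FALSE)
}

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a matched-pair expression cohort
#'
#' The expression TSV has gene rows and sample columns with a leading
#' \code{gene} column; the sample map TSV has columns \code{sample},
#' \code{case}, \code{tissue}.  The reader validates unique gene ids and a
#' complete sample join, and returns a [PairedExpressionCohort-class].
#'
#' @param exprPath,mapPath File paths.
#' @return \code{readPairedCohort}: a [PairedExpressionCohort-class].
#' @export
readPairedCohort <- function(exprPath, mapPath) {
    ex <- .readTSV(exprPath)
    if (colnames(ex)[1L] != "gene") {
        stop("expression TSV must have a leading 'gene' column")
    }
    if (anyDuplicated(ex$gene)) {
        stop("duplicate gene ids in ", exprPath, ": ",
            paste(unique(ex$gene[duplicated(ex$gene)]), collapse = ", "))
    }
    m <- as.matrix(ex[, -1L, drop = FALSE])
    rownames(m) <- ex$gene
    sm <- .readTSV(mapPath)
    if (!all(c("sample", "case", "tissue") %in% colnames(sm))) {
        stop("sample map must have columns sample, case, tissue")
    }
    unmatched <- setdiff(colnames(m), sm$sample)
    if (length(unmatched)) {
        stop("samples missing from sample map: ",
            paste(unmatched, collapse = ", "))
    }
    sm <- sm[match(colnames(m), sm$sample), ]
    pairedCohort(m, case = sm$case, tissue = sm$tissue)
}

#' @rdname readPairedCohort
#' @param cohort A [PairedExpressionCohort-class] to write.
#' @return \code{writePairedCohort}: the two paths, invisibly.
#' @export
writePairedCohort <- function(cohort, exprPath, mapPath) {
    stopifnot(is(cohort, "PairedExpressionCohort"))
    m <- exprValues(cohort)
    .writeTSV(data.frame(gene = rownames(m), m, check.names = FALSE),
        exprPath)
    .writeTSV(data.frame(sample = colnames(cohort),
        case = caseIds(cohort), tissue = tissueLabels(cohort)), mapPath)
    invisible(c(exprPath, mapPath))
}

#' Read / write a clinical survival table
#'
#' Columns: \code{patient}, \code{time}, \code{event}, plus any covariates
#' (\code{residual_disease}, \code{treated}, ...).
#'
#' @param path File path.
#' @return \code{readClinicalTable}: a data.frame.
#' @export
readClinicalTable <- function(path) {
    df <- .readTSV(path)
    need <- c("patient", "time", "event")
    if (!all(need %in% colnames(df))) {
        stop("clinical table must have columns ",
            paste(need, collapse = ", "))
    }
    if (any(df$time <= 0) || !all(df$event %in% c(0, 1))) {
        stop("clinical table needs time > 0 and binary event")
    }
    df
}

#' @rdname readClinicalTable
#' @param df Clinical data.frame to write.
#' @export
writeClinicalTable <- function(df, path) .writeTSV(df, path)

#' Read / write an aCGH probe track
#'
#' TSV columns \code{chrom}, \code{start}, \code{end} (0-based half-open),
#' \code{probe}, \code{log10_ratio}.  In memory the track is a 1-based
#' \linkS4class{GRanges}.
#'
#' @param path File path.
#' @return \code{readProbeTrack}: a sorted \linkS4class{GRanges}.
#' @export
readProbeTrack <- function(path) {
    df <- .readTSV(path)
    need <- c("chrom", "start", "end", "probe", "log10_ratio")
    if (!all(need %in% colnames(df))) {
        stop("probe track must have columns ", paste(need, collapse = ", "))
    }
    if (any(!is.finite(df$log10_ratio))) stop("log10 ratios must be finite")
    gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end),
        probe = df$probe, log10_ratio = df$log10_ratio)
    GenomicRanges::sort(gr)
}

#' @rdname readProbeTrack
#' @param track \linkS4class{GRanges} with \code{probe} and
#'   \code{log10_ratio} mcols.
#' @export
writeProbeTrack <- function(track, path) {
    stopifnot(is(track, "GRanges"))
    .writeTSV(data.frame(
        chrom = as.character(seqnames(track)),
        start = GenomicRanges::start(track) - 1L,
        end = GenomicRanges::end(track),
        probe = mcols(track)$probe,
        log10_ratio = mcols(track)$log10_ratio), path)
}

#' Read gene models from a BED file
#'
#' @param path BED file (0-based half-open; name column used as gene id).
#' @return \linkS4class{GRanges} with a \code{name} mcol.
#' @export
readGeneModels <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(mcols(gr)$name)) stop("BED file lacks a name column")
    gr
}

#' Write segments in IGV SEG format
#'
#' Columns \code{Sample}, \code{Chromosome}, \code{Start}, \code{End}
#' (1-based inclusive), \code{Num_Probes}, \code{Segment_Mean}.
#'
#' @param segments Segment \linkS4class{GRanges} from [segmentCBS()].
#' @param sample Sample identifier for the first column.
#' @param path Output path.
#' @export
writeSegTable <- function(segments, sample, path) {
    stopifnot(is(segments, "GRanges"))
    .writeTSV(data.frame(
        Sample = sample,
        Chromosome = as.character(seqnames(segments)),
        Start = GenomicRanges::start(segments),
        End = GenomicRanges::end(segments),
        Num_Probes = mcols(segments)$n_probes,
        Segment_Mean = mcols(segments)$seg_mean), path)
}

#' Read / write a signature as JSON
#'
#' @param signature A [MetSignature-class].
#' @param path File path.
#' @return \code{readSignatureJSON}: a [MetSignature-class].
#' @export
writeSignatureJSON <- function(signature, path) {
    stopifnot(is(signature, "MetSignature"))
    jsonlite::write_json(list(
        genes = signatureGenes(signature),
        directions = unname(signatureDirections(signature)),
        threshold = riskThreshold(signature)), path,
        auto_unbox = FALSE, pretty = TRUE)
    invisible(path)
}

#' @rdname writeSignatureJSON
#' @export
readSignatureJSON <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    metSignature(x$genes, x$directions, threshold = x$threshold)
}

#' Read / write a staining table
#'
#' Columns \code{case}, \code{tissue}, \code{percent}, optional
#' \code{assay}.
#'
#' @param path File path.
#' @export
readStainingTable <- function(path) {
    df <- .readTSV(path)
    if (!all(c("case", "tissue", "percent") %in% colnames(df))) {
        stop("staining table must have columns case, tissue, percent")
    }
    df
}

#' @rdname readStainingTable
#' @param df Staining data.frame.
#' @export
writeStainingTable <- function(df, path) .writeTSV(df, path)
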