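#' @name accessors
#' @title Accessors for metsig classes
#' @description Small accessor generics: signature genes, directions and the
#'   high-risk threshold of a [MetSignature-class]; case identifiers, tissue
#'   labels, the log2 expression matrix and the per-case metastasis-minus-
#'   primary difference matrix of a [PairedExpressionCohort-class].
#' @param x A metsig object.
#' @return Vectors/matrices as described per method.
NULL

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname accessors
#' @export
setGeneric("signatureDirections",
    function(x) standardGeneric("signatureDirections"))

#' @rdname accessors
#' @export
setGeneric("riskThreshold", function(x) standardGeneric("riskThreshold"))

#' @rdname accessors
#' @export
setGeneric("caseIds", function(x) standardGeneric("caseIds"))

#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("pairedDiffs", function(x) standardGeneric("pairedDiffs"))

#' @rdname accessors
#' @export
setMethod("signatureGenes", "MetSignature", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("signatureDirections", "MetSignature",
    function(x) setNames(x@directions, x@genes))

#' @rdname accessors
#' @export
setMethod("riskThreshold", "MetSignature", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("caseIds", "PairedExpressionCohort",
    function(x) colData(x)$case)

#' @rdname accessors
#' @export
setMethod("tissueLabels", "PairedExpressionCohort",
    function(x) colData(x)$tissue)

#' @rdname accessors
#' @export
setMethod("exprValues", "PairedExpressionCohort",
    function(x) assay(x, "log2expr"))

#' @rdname accessors
#' @export
setMethod("pairedDiffs", "PairedExpressionCohort", function(x) {
    cd <- colData(x)
    cases <- unique(cd$case)
    m <- assay(x, "log2expr")
    met <- m[, match(paste0(cases, ".metastasis"),
        paste0(cd$case, ".", cd$tissue)), drop = FALSE]
    pri <- m[, match(paste0(cases, ".primary"),
        paste0(cd$case, ".", cd$tissue)), drop = FALSE]
    d <- met - pri
    colnames(d) <- cases
    d
})
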