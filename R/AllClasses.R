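#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowRanges colData
NULL

CNV_TYPES <- c("DEL", "DUP", "mCNV")

#' CNVDosage: integer copy-number dosages with CNV coordinates
#'
#' An extension of \linkS4class{RangedSummarizedExperiment} holding one
#' assay, \code{"dosage"}: an integer matrix of copy numbers (CNVs x
#' samples) for diploid individuals, baseline (non-carrier) dosage 2.
#' \code{rowRanges} carry the CNV coordinates as 1-based, fully closed
#' intervals, with a \code{cnv_type} metadata column taking values
#' \code{DEL} (only deletion alleles segregate), \code{DUP} (only
#' duplication alleles) or \code{mCNV} (both).
#'
#' @aliases CNVDosage-class
#' @exportClass CNVDosage
setClass("CNVDosage", contains = "RangedSummarizedExperiment")

setValidity("CNVDosage", function(object) {
    msg <- character()
    if (!"dosage" %in% names(SummarizedExperiment::assays(object)))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        if (any(!is.finite(d)))
            msg <- c(msg, "dosage values must be finite")
        else {
            if (any(d < 0)) msg <- c(msg, "dosage values must be non-negative")
            if (any(d != round(d)))
                msg <- c(msg, "dosage values must be integers")
        }
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (!"cnv_type" %in% names(S4Vectors::mcols(rr)))
        msg <- c(msg, "rowRanges must carry a 'cnv_type' column")
    else if (!all(S4Vectors::mcols(rr)$cnv_type %in% CNV_TYPES))
        msg <- c(msg, sprintf("cnv_type must be one of %s",
                              paste(CNV_TYPES, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate cnv_id in rownames")
    if (length(msg)) msg else TRUE
})

#' Construct a CNVDosage object
#'
#' @param dosage integer matrix, CNVs x samples; rownames are CNV ids,
#'   colnames are sample ids.
#' @param chrom,start,end per-CNV coordinates (1-based, closed).
#' @param cnv_type per-CNV type: \code{"DEL"}, \code{"DUP"} or
#'   \code{"mCNV"}.
#' @return A \linkS4class{CNVDosage}.
#' @examples
#' d <- CNVDosage(matrix(c(2L, 1L, 2L), 1, 3,
#'                       dimnames = list("DEL1", c("s1", "s2", "s3"))),
#'                chrom = "chr1", start = 100, end = 200, cnv_type = "DEL")
#' dosage(d)
#' @export
CNVDosage <- function(dosage, chrom, start, end, cnv_type) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (is.null(rownames(dosage)))
        stop("dosage matrix must have CNV ids as rownames")
    if (any(end < start))
        stop("CNV intervals must satisfy start <= end (1-based, closed)")
    rr <- GenomicRanges::GRanges(
        seqnames = as.character(chrom),
        ranges = IRanges::IRanges(start = as.integer(start),
                                  end = as.integer(end)),
        cnv_type = as.character(cnv_type))
    names(rr) <- rownames(dosage)
    new("CNVDosage",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(dosage = dosage), rowRanges = rr))
}

#' @describeIn CNVDosage Extract the integer dosage matrix.
#' @param object,x a \code{CNVDosage}.
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' @rdname CNVDosage
#' @export
setMethod("dosage", "CNVDosage", function(object)
    SummarizedExperiment::assay(object, "dosage"))

#' @describeIn CNVDosage Per-CNV type labels (DEL / DUP / mCNV).
#' @export
setGeneric("cnvType", function(object) standardGeneric("cnvType"))

#' @rdname CNVDosage
#' @export
setMethod("cnvType", "CNVDosage", function(object) {
    tp <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))$cnv_type
    stats::setNames(as.character(tp), rownames(object))
})

setMethod("show", "CNVDosage", function(object) {
    cat(sprintf("CNVDosage: %d CNVs x %d samples\n",
                nrow(object), ncol(object)))
    tp <- table(cnvType(object))
    cat("  types:", paste(sprintf("%s=%d", names(tp), tp), collapse = " "),
        "\n")
    carr <- sum(dosage(object) != 2L)
    cat(sprintf("  non-reference dosage cells: %d (baseline = 2)\n", carr))
})
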