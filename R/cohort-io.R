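#' @importFrom utils read.delim write.table
NULL

PHENO_COLS <- c("sample_id", "aod", "sex", "cogdx", "braaksc", "ceradsc")

## Full-precision numeric formatting so that write -> read round-trips
## reproduce doubles exactly (17 significant digits suffice for IEEE-754).
.fmt_num <- function(x) {
    out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
    ## strip trailing zeros that %g already avoids; keep integers clean
    ifelse(x == round(x) & abs(x) < 1e15, sprintf("%d", as.integer(round(x))),
           out)
}

#' Read a CNV dosage matrix from TSV
#'
#' Expects a header row and the leading columns \code{cnv_id}, \code{chrom},
#' \code{start}, \code{end}, \code{cnv_type}, followed by one integer column
#' per sample. Coordinates are 1-based, fully closed.
#'
#' @param path path to the TSV file.
#' @param verbose log row/column counts via \code{message}.
#' @return A \linkS4class{CNVDosage}.
#' @export
readDosageMatrix <- function(path, verbose = TRUE) {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character")
    need <- c("cnv_id", "chrom", "start", "end", "cnv_type")
    if (!all(need %in% colnames(df)[seq_along(need)]))
        stop("dosage TSV must start with columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(df$cnv_id))
        stop("duplicate cnv_id: ",
             paste(unique(df$cnv_id[duplicated(df$cnv_id)]), collapse = ", "))
    samp <- setdiff(colnames(df), need)
    if (!length(samp)) stop("no sample columns found")
    cells <- as.matrix(df[, samp, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
    bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)
    if (nrow(bad) > 0) {
        stop(sprintf(
            "non-integer dosage cell at CNV '%s', sample '%s' (value '%s')",
            df$cnv_id[bad[1, 1]], samp[bad[1, 2]],
            cells[bad[1, 1], bad[1, 2]]))
    }
    dos <- matrix(as.integer(num), nrow = nrow(df),
                  dimnames = list(df$cnv_id, samp))
    obj <- CNVDosage(dos, chrom = df$chrom,
                     start = as.integer(df$start), end = as.integer(df$end),
                     cnv_type = df$cnv_type)
    if (verbose)
        message(sprintf("readDosageMatrix: %d CNVs x %d samples",
                        nrow(obj), ncol(obj)))
    obj
}

#' Write a CNV dosage matrix to TSV
#'
#' @param x a \linkS4class{CNVDosage}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDosageMatrix <- function(x, path) {
    rr <- SummarizedExperiment::rowRanges(x)
    df <- data.frame(cnv_id = rownames(x),
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     start = GenomicRanges::start(rr),
                     end = GenomicRanges::end(rr),
                     cnv_type = cnvType(x),
                     dosage(x), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read the clinical phenotype table
#'
#' Expects TSV columns \code{sample_id}, \code{aod}, \code{sex},
#' \code{cogdx}, \code{braaksc}, \code{ceradsc}. Ages of death above
#' \code{aodCap} are replaced by \code{aodCap} (default 90). Sex may be
#' coded 0/1 (Female = 0, Male = 1) or as F/M / Female/Male strings, which
#' are recoded. The diagnosis group is derived from the clinical consensus
#' diagnosis: \code{NL} for cogdx 1, \code{AD} for cogdx 2-5. The CERAD
#' plaque score is expected on the recoded scale 1 = Normal ... 4 =
#' definite AD; set \code{ceradscRecoded = FALSE} for the raw scale
#' (4 = Normal ... 1 = definite), which is then recoded as 5 - raw.
#'
#' @param path path to the TSV file.
#' @param aodCap cap for age of death, in years.
#' @param ceradscRecoded whether the ceradsc column is already on the
#'   recoded 1-4 scale.
#' @return A \link[S4Vectors]{DataFrame} with rownames = sample ids and
#'   columns \code{aod}, \code{sex}, \code{cogdx}, \code{braaksc},
#'   \code{ceradsc}, \code{group}.
#' @export
readPhenotypes <- function(path, aodCap = 90, ceradscRecoded = TRUE) {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
    miss <- setdiff(PHENO_COLS, colnames(df))
    if (length(miss))
        stop("phenotype TSV missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
    if (any(is.na(df$aod))) stop("missing aod for sample(s): ",
        paste(df$sample_id[is.na(df$aod)], collapse = ", "))
    sex <- df$sex
    if (is.character(sex))
        sex <- c(F = 0, M = 1, Female = 0, Male = 1)[sex]
    sex <- as.integer(sex)
    if (any(is.na(sex) | !sex %in% 0:1))
        stop("sex must code Female = 0, Male = 1")
    cogdx <- as.integer(df$cogdx)
    if (any(is.na(cogdx) | cogdx < 1L | cogdx > 5L))
        stop("cogdx outside 1-5 for sample(s): ",
             paste(df$sample_id[is.na(cogdx) | cogdx < 1 | cogdx > 5],
                   collapse = ", "))
    cer <- as.integer(df$ceradsc)
    if (!ceradscRecoded) cer <- 5L - cer
    if (any(is.na(cer) | cer < 1L | cer > 4L))
        stop("ceradsc outside the recoded 1-4 scale")
    out <- S4Vectors::DataFrame(
        aod = pmin(as.numeric(df$aod), aodCap),
        sex = sex,
        cogdx = cogdx,
        braaksc = as.integer(df$braaksc),
        ceradsc = cer,
        group = ifelse(cogdx == 1L, "NL", "AD"),
        row.names = as.character(df$sample_id))
    out
}

#' Write a phenotype table to TSV
#'
#' @param pheno a phenotype \code{DataFrame} as returned by
#'   \code{\link{readPhenotypes}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(pheno, path) {
    df <- data.frame(sample_id = rownames(pheno),
                     aod = .fmt_num(pheno$aod),
                     sex = pheno$sex, cogdx = pheno$cogdx,
                     braaksc = pheno$braaksc, ceradsc = pheno$ceradsc)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a log2 expression matrix from TSV
#'
#' Genes in rows (first column = gene id), samples in columns, values on
#' the log2 scale; all values must be finite.
#'
#' @param path path to the TSV file.
#' @param verbose log dimensions via \code{message}.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with one
#'   assay \code{"log2expr"}.
#' @export
readExpressionMatrix <- function(path, verbose = TRUE) {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
    genes <- as.character(df[[1]])
    if (anyDuplicated(genes)) stop("duplicate gene ids")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) storage.mode(m) <- "numeric"
    rownames(m) <- genes
    if (any(!is.finite(m))) {
        idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
        stop(sprintf("non-finite expression value for gene '%s', sample '%s'",
                     genes[idx[1]], colnames(m)[idx[2]]))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = m))
    if (verbose)
        message(sprintf("readExpressionMatrix: %d genes x %d samples",
                        nrow(se), ncol(se)))
    se
}

#' Write an expression matrix to TSV
#'
#' @param expr a \code{SummarizedExperiment} with assay \code{"log2expr"},
#'   or a plain numeric matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(expr, path) {
    m <- .expr_matrix(expr)
    df <- data.frame(gene_id = rownames(m),
                     vapply(seq_len(ncol(m)),
                            function(j) .fmt_num(m[, j]),
                            character(nrow(m))),
                     check.names = FALSE)
    colnames(df) <- c("gene_id", colnames(m))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.expr_matrix <- function(expr) {
    if (methods::is(expr, "SummarizedExperiment"))
        SummarizedExperiment::assay(expr, 1)
    else as.matrix(expr)
}

#' Harmonize sample order between assay objects and phenotypes
#'
#' Restricts both objects to the intersection of their sample ids, in the
#' order the phenotype table lists them (stable order). Errors on an empty
#' intersection.
#'
#' @param x a \code{CNVDosage}, \code{SummarizedExperiment} or matrix with
#'   sample columns.
#' @param pheno a phenotype \code{DataFrame}.
#' @return A list with elements \code{x} and \code{pheno}, both restricted
#'   to the shared samples.
#' @export
harmonizeSamples <- function(x, pheno) {
    ids <- intersect(rownames(pheno), colnames(x))
    if (!length(ids))
        stop("no samples shared between assay object and phenotype table")
    x2 <- if (is.matrix(x)) x[, ids, drop = FALSE] else x[, ids]
    list(x = x2, pheno = pheno[ids, , drop = FALSE])
}
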