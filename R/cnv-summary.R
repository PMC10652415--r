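#' Allele and carrier frequency summary per CNV
#'
#' For each CNV, deletion allele count is \code{sum(max(0, 2 - dosage))},
#' duplication allele count is \code{sum(max(0, dosage - 2))}, the allele
#' number is \code{2 * n_samples}, allele frequency is AC / AN, and a
#' carrier is any sample with dosage != 2 (either direction).
#'
#' @param x a \linkS4class{CNVDosage}.
#' @return A data.frame with one row per CNV: \code{cnv_id},
#'   \code{allele_count_total}, \code{allele_count_del},
#'   \code{allele_count_dup}, \code{allele_number},
#'   \code{allele_frequency}, \code{carrier_count},
#'   \code{carrier_frequency}.
#' @examples
#' d <- CNVDosage(matrix(c(2L, 1L, 2L), 1, 3,
#'                       dimnames = list("DEL1", c("a", "b", "c"))),
#'                "chr1", 1, 100, "DEL")
#' summarizeFrequencies(d)
#' @export
summarizeFrequencies <- function(x) {
    d <- dosage(x)
    if (!nrow(d)) stop("empty dosage matrix")
    ac_del <- rowSums(pmax(2L - d, 0L))
    ac_dup <- rowSums(pmax(d - 2L, 0L))
    an <- 2L * ncol(d)
    carriers <- rowSums(d != 2L)
    data.frame(cnv_id = rownames(d),
               allele_count_total = ac_del + ac_dup,
               allele_count_del = ac_del,
               allele_count_dup = ac_dup,
               allele_number = an,
               allele_frequency = (ac_del + ac_dup) / an,
               carrier_count = carriers,
               carrier_frequency = carriers / ncol(d),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Carrier-frequency difference between diagnosis groups
#'
#' Per CNV, builds the 2x2 table (carrier / non-carrier x AD / NL) and
#' runs a Pearson chi-square test of independence. No continuity
#' correction by default, matching the plain chi-square test.
#'
#' @param x a \linkS4class{CNVDosage}.
#' @param pheno phenotype \code{DataFrame} with a \code{group} column.
#' @param correct apply Yates continuity correction.
#' @return A data.frame per CNV with the four table counts
#'   (\code{carrier_ad}, \code{carrier_nl}, \code{noncarrier_ad},
#'   \code{noncarrier_nl}), \code{chi2} and \code{p_value}.
#' @export
groupFrequencyTest <- function(x, pheno, correct = FALSE) {
    h <- harmonizeSamples(x, pheno)
    d <- dosage(h$x)
    grp <- h$pheno$group
    if (!all(c("AD", "NL") %in% grp))
        stop("both AD and NL groups must be nonempty")
    ad <- grp == "AD"
    res <- lapply(seq_len(nrow(d)), function(i) {
        carrier <- d[i, ] != 2L
        tab <- matrix(c(sum(carrier & ad), sum(carrier & !ad),
                        sum(!carrier & ad), sum(!carrier & !ad)),
                      2, 2, byrow = TRUE)
        ct <- suppressWarnings(
            stats::chisq.test(tab, correct = correct))
        chi2 <- unname(ct$statistic)
        p <- unname(ct$p.value)
        if (is.na(chi2)) { chi2 <- 0; p <- 1 }  # degenerate margins
        data.frame(cnv_id = rownames(d)[i],
                   carrier_ad = tab[1, 1], carrier_nl = tab[1, 2],
                   noncarrier_ad = tab[2, 1], noncarrier_nl = tab[2, 2],
                   chi2 = chi2, p_value = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Read a BED-like external CNV set
#'
#' Tab-separated columns \code{chrom}, \code{start}, \code{end},
#' \code{type}, \code{source_id}; coordinates 1-based, closed.
#'
#' @param path file path.
#' @return A data.frame.
#' @export
readExternalCnvDb <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "type", "source_id")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("external CNV set missing columns: ",
             paste(miss, collapse = ", "))
    df
}

## reciprocal overlap of 1-based closed intervals on the same chromosome
.recip_overlap <- function(qs, qe, ds, de) {
    ov <- pmax(0, pmin(qe, de) - pmax(qs, ds) + 1)
    cbind(query = ov / (qe - qs + 1), db = ov / (de - ds + 1))
}

#' Validate CNVs against an external CNV set by reciprocal overlap
#'
#' A query CNV is validated when some database record of compatible type
#' covers more than 50% of it AND the query covers more than 50% of the
#' record (strict reciprocal-overlap rule; a boundary value of exactly
#' 0.5 fails). By default an mCNV query is type-compatible with any
#' database type (a mixed locus carries both allele classes), while DEL
#' and DUP require an exact type match; set \code{mcnv_matches_any =
#' FALSE} to require exact matches for mCNV too. Per query the single
#' best database record (largest minimal reciprocal overlap among
#' type-compatible records) is reported.
#'
#' @param x a \linkS4class{CNVDosage} (queries).
#' @param db external CNV set data.frame as from
#'   \code{\link{readExternalCnvDb}}.
#' @param min_recip reciprocal-overlap threshold (strictly exceeded on
#'   both fractions).
#' @param mcnv_matches_any whether mCNV queries match any database type.
#' @return A data.frame per query: \code{query_id}, \code{db_id},
#'   \code{overlap_query}, \code{overlap_db}, \code{same_type},
#'   \code{validated}. Queries with no type-compatible overlapping record
#'   get \code{db_id = NA} and zero overlaps.
#' @export
validateAgainstDb <- function(x, db, min_recip = 0.5,
                              mcnv_matches_any = TRUE) {
    stopifnot(nrow(x) > 0, nrow(db) > 0)
    if (any(db$end < db$start))
        stop("malformed database interval (start > end)")
    rr <- SummarizedExperiment::rowRanges(x)
    qtype <- cnvType(x)
    qs <- GenomicRanges::start(rr); qe <- GenomicRanges::end(rr)
    qchr <- as.character(GenomicRanges::seqnames(rr))
    out <- lapply(seq_along(rr), function(i) {
        compat <- if (qtype[i] == "mCNV" && mcnv_matches_any) {
            rep(TRUE, nrow(db))
        } else db$type == qtype[i]
        cand <- which(db$chrom == qchr[i] & compat)
        if (length(cand)) {
            ov <- .recip_overlap(qs[i], qe[i],
                                 db$start[cand], db$end[cand])
            best <- which.max(pmin(ov[, "query"], ov[, "db"]))
            j <- cand[best]
            oq <- ov[best, "query"]; od <- ov[best, "db"]
        } else {
            j <- NA_integer_; oq <- 0; od <- 0
        }
        data.frame(query_id = names(rr)[i],
                   db_id = if (is.na(j)) NA_character_ else db$source_id[j],
                   overlap_query = oq, overlap_db = od,
                   same_type = if (is.na(j)) FALSE else
                       (db$type[j] == qtype[i] ||
                        (qtype[i] == "mCNV" && mcnv_matches_any)),
                   validated = min(oq, od) > min_recip && !is.na(j),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
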