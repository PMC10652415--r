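#' @importFrom limma lmFit eBayes
NULL

TRAIT_NAMES <- c("cogdx", "braaksc", "ceradsc")

.check_trait <- function(trait) {
    trait <- match.arg(trait, TRAIT_NAMES)
    trait
}

#' Remove disease-severity signal from expression
#'
#' Fits, per gene, an ordinary-least-squares model of log2 expression on
#' intercept + one pathology trait (via \code{limma::lmFit}) and returns
#' the residuals. Residuals are orthogonal to the trait, so downstream
#' gene-longevity screens are not confounded by disease severity. The
#' per-gene trait coefficient (alpha) and intercept are kept in
#' \code{rowData} for audit.
#'
#' @param expr \code{SummarizedExperiment} (assay \code{"log2expr"}) or
#'   numeric matrix, genes x samples.
#' @param pheno phenotype \code{DataFrame}; samples are harmonized with
#'   \code{expr} first.
#' @param trait one of \code{"cogdx"}, \code{"braaksc"},
#'   \code{"ceradsc"}.
#' @return A \code{SummarizedExperiment} with assay \code{"resid"},
#'   rowData columns \code{alpha} (trait slope) and \code{intercept}, and
#'   \code{metadata(x)$trait_used}.
#' @export
residualize <- function(expr, pheno, trait = "cogdx") {
    trait <- .check_trait(trait)
    h <- harmonizeSamples(expr, pheno)
    m <- .expr_matrix(h$x)
    tv <- as.numeric(h$pheno[[trait]])
    if (stats::sd(tv) == 0)
        stop("trait '", trait, "' is constant across samples; ",
             "residualization is undefined")
    design <- cbind(Intercept = 1, trait = tv)
    fit <- limma::lmFit(m, design)
    resid <- m - fit$coefficients %*% t(design)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(resid = resid),
        rowData = S4Vectors::DataFrame(
            alpha = unname(fit$coefficients[, "trait"]),
            intercept = unname(fit$coefficients[, "Intercept"]),
            row.names = rownames(m)))
    S4Vectors::metadata(se)$trait_used <- trait
    se
}

#' Differential expression between AD and NL groups
#'
#' Per-gene two-group linear-model contrast of the AD vs NL diagnosis
#' groups via \code{limma::lmFit}. \code{log_fc} is mean(AD) - mean(NL)
#' on the log2 scale. By default the classical (unmoderated) pooled-
#' variance t statistic is reported; \code{moderated = TRUE} switches to
#' the empirical-Bayes moderated t. Significance calls require both
#' FDR < \code{fdr_cut} and |logFC| > \code{lfc_cut}.
#'
#' @param expr expression (\code{SummarizedExperiment} or matrix).
#' @param pheno phenotype \code{DataFrame} with \code{group}.
#' @param fdr_cut,lfc_cut significance cutoffs (defaults 0.05 and 1).
#' @param moderated use limma's moderated t instead of the classical t.
#' @return A data.frame: \code{gene_id}, \code{log_fc}, \code{t_stat},
#'   \code{p_value}, \code{fdr}, \code{significant}.
#' @export
differentialExpression <- function(expr, pheno, fdr_cut = 0.05,
                                   lfc_cut = 1, moderated = FALSE) {
    h <- harmonizeSamples(expr, pheno)
    m <- .expr_matrix(h$x)
    grp <- h$pheno$group
    if (sum(grp == "AD") < 2 || sum(grp == "NL") < 2)
        stop("both groups need at least 2 samples")
    design <- cbind(Intercept = 1, AD = as.numeric(grp == "AD"))
    fit <- limma::lmFit(m, design)
    logfc <- fit$coefficients[, "AD"]
    df <- fit$df.residual
    if (moderated) {
        eb <- limma::eBayes(fit)
        t_stat <- eb$t[, "AD"]
        p <- eb$p.value[, "AD"]
    } else {
        t_stat <- logfc / (fit$stdev.unscaled[, "AD"] * fit$sigma)
        p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
    }
    ## genes with (numerically) zero residual variance carry no sampling
    ## evidence: zero difference -> p = 1 by convention
    degen <- !is.finite(t_stat) | fit$sigma < 1e-12
    zero_fc <- abs(logfc) < 1e-12
    t_stat[degen & zero_fc] <- 0
    p[degen & zero_fc] <- 1
    p[degen & !zero_fc] <- 0
    fdr <- stats::p.adjust(p, method = "BH")
    data.frame(gene_id = rownames(m), log_fc = logfc, t_stat = t_stat,
               p_value = p, fdr = fdr,
               significant = fdr < fdr_cut & abs(logfc) > lfc_cut,
               row.names = NULL, stringsAsFactors = FALSE)
}
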