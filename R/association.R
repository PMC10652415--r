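#' Covariate-adjusted linear association of a response and a predictor
#'
#' Ordinary least squares of \code{y} on intercept + \code{x} +
#' \code{covariates}; reports the slope for \code{x} with its standard
#' error, t statistic and two-sided p-value from the Student t
#' distribution on \code{n - ncol(design)} residual degrees of freedom.
#' This is exactly the linear model a matrix-eQTL engine fits per test.
#'
#' @param y numeric response vector.
#' @param x numeric predictor vector (non-constant).
#' @param covariates optional numeric matrix (columns = covariates).
#' @return A one-row data.frame: \code{beta}, \code{se}, \code{t_stat},
#'   \code{p_value}, \code{df}.
#' @examples
#' linearAssoc(3 * (1:10), 1:10)
#' @export
linearAssoc <- function(y, x, covariates = NULL) {
    stopifnot(length(y) == length(x))
    if (stats::sd(x) == 0) stop("predictor x is constant")
    X <- cbind(`(Intercept)` = 1, x = x)
    if (!is.null(covariates)) {
        covariates <- as.matrix(covariates)
        if (is.null(colnames(covariates)))
            colnames(covariates) <-
                paste0("cov", seq_len(ncol(covariates)))
        stopifnot(nrow(covariates) == length(y))
        X <- cbind(X, covariates)
    }
    n <- length(y); p <- ncol(X)
    if (n <= p) stop("need more observations than design columns")
    qrX <- qr(X)
    if (qrX$rank < p) {
        drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
        stop("rank-deficient design; collinear column(s): ",
             paste(drop, collapse = ", "))
    }
    coef <- qr.coef(qrX, y)
    res <- y - X %*% coef
    df <- n - p
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    beta <- coef["x"]
    t_stat <- beta / se
    data.frame(beta = unname(beta), se = se, t_stat = unname(t_stat),
               p_value = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
               df = df, row.names = NULL)
}

.trait_design <- function(pheno, trait) {
    cbind(sex = as.numeric(pheno$sex),
          trait = as.numeric(pheno[[trait]]))
}

#' CNV-longevity association scan
#'
#' Per CNV, fits AOD ~ dosage + sex + pathology trait by OLS. CNVs whose
#' dosage is constant across the cohort (zero standard deviation) are
#' excluded from testing. P-values are BH-adjusted across the CNVs
#' actually tested.
#'
#' @param x a \linkS4class{CNVDosage}.
#' @param pheno phenotype \code{DataFrame}.
#' @param trait pathology trait used as the disease-status covariate.
#' @param fdr_cut significance threshold on the BH FDR.
#' @return A data.frame of association results (one row per tested CNV):
#'   \code{unit_a} (cnv id), \code{unit_b} (\code{"AOD"}), \code{beta},
#'   \code{se}, \code{t_stat}, \code{p_value}, \code{fdr},
#'   \code{trait_covariate}, \code{significant}.
#' @export
cnvAodScan <- function(x, pheno, trait = "cogdx", fdr_cut = 0.05) {
    trait <- .check_trait(trait)
    h <- harmonizeSamples(x, pheno)
    d <- dosage(h$x)
    keep <- apply(d, 1, stats::sd) > 0
    d <- d[keep, , drop = FALSE]
    cov <- .trait_design(h$pheno, trait)
    y <- h$pheno$aod
    rows <- lapply(seq_len(nrow(d)), function(i)
        linearAssoc(y, as.numeric(d[i, ]), cov))
    out <- do.call(rbind, rows)
    out <- data.frame(unit_a = rownames(d), unit_b = "AOD",
                      out[c("beta", "se", "t_stat", "p_value")],
                      fdr = stats::p.adjust(out$p_value, "BH"),
                      trait_covariate = trait,
                      stringsAsFactors = FALSE)
    out$significant <- out$fdr < fdr_cut
    out
}

#' Consensus significant CNVs across the three pathology traits
#'
#' @param sets_by_trait named list (names \code{cogdx}, \code{braaksc},
#'   \code{ceradsc}) of character vectors of significant CNV ids.
#' @return The intersection of the three sets (character vector).
#' @export
consensusAcrossTraits <- function(sets_by_trait) {
    miss <- setdiff(TRAIT_NAMES, names(sets_by_trait))
    if (length(miss))
        stop("missing trait key(s): ", paste(miss, collapse = ", "))
    Reduce(intersect, sets_by_trait[TRAIT_NAMES])
}

#' CNV-expression (eQTL-style) association scan
#'
#' For every (CNV, gene) pair, regresses gene expression on dosage +
#' sex + pathology trait on the samples shared by all inputs, with a
#' single BH FDR adjustment across all tested pairs jointly.
#'
#' @param x a \linkS4class{CNVDosage}, typically restricted to the
#'   consensus longevity-associated CNVs.
#' @param expr expression \code{SummarizedExperiment} or matrix.
#' @param pheno phenotype \code{DataFrame}.
#' @param trait pathology trait covariate.
#' @param fdr_cut significance threshold on the BH FDR.
#' @return A data.frame with one row per tested pair: \code{unit_a}
#'   (cnv id), \code{unit_b} (gene id), \code{beta}, \code{se},
#'   \code{t_stat}, \code{p_value}, \code{fdr}, \code{trait_covariate},
#'   \code{significant}.
#' @export
cnvGeneScan <- function(x, expr, pheno, trait = "cogdx", fdr_cut = 0.05) {
    trait <- .check_trait(trait)
    m <- .expr_matrix(expr)
    ids <- Reduce(intersect, list(rownames(pheno), colnames(x), colnames(m)))
    if (!length(ids)) stop("no samples shared by dosage, expression and ",
                           "phenotypes")
    ids <- rownames(pheno)[rownames(pheno) %in% ids]  # stable order
    d <- dosage(x)[, ids, drop = FALSE]
    m <- m[, ids, drop = FALSE]
    ph <- pheno[ids, , drop = FALSE]
    cov <- .trait_design(ph, trait)
    keep <- apply(d, 1, stats::sd) > 0
    d <- d[keep, , drop = FALSE]
    res <- lapply(seq_len(nrow(d)), function(i) {
        design <- cbind(`(Intercept)` = 1, x = as.numeric(d[i, ]), cov)
        fit <- limma::lmFit(m, design)
        beta <- fit$coefficients[, "x"]
        se <- fit$stdev.unscaled[, "x"] * fit$sigma
        t_stat <- beta / se
        data.frame(unit_a = rownames(d)[i], unit_b = rownames(m),
                   beta = unname(beta), se = unname(se),
                   t_stat = unname(t_stat),
                   p_value = 2 * stats::pt(abs(t_stat), fit$df.residual,
                                           lower.tail = FALSE),
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    out <- do.call(rbind, res)
    out$fdr <- stats::p.adjust(out$p_value, "BH")
    out$trait_covariate <- trait
    out$significant <- out$fdr < fdr_cut
    out
}

## Spearman rho with average ranks plus the t-approximation p-value
## (tie-corrected, identical to Pearson on ranks).
.spearman <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    rho <- stats::cor(ra, rb)
    n <- length(a)
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (abs(rho) >= 1) 0 else
        2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
    c(rho = rho, p = p)
}

#' Gene-longevity Spearman screen
#'
#' Per gene, the tie-corrected Spearman rank correlation between
#' (severity-residualized) expression and capped AOD, with a two-sided
#' t-approximation p-value and BH FDR across all genes (genome-wide).
#' Genes with constant expression are skipped with a warning.
#'
#' @param resid residualized expression (\code{SummarizedExperiment} from
#'   \code{\link{residualize}}, or matrix).
#' @param pheno phenotype \code{DataFrame}.
#' @param fdr_cut significance threshold on the BH FDR.
#' @return A data.frame per gene: \code{unit_a} (gene id), \code{unit_b}
#'   (\code{"AOD"}), \code{beta} (the Spearman rho), \code{p_value},
#'   \code{fdr}, \code{significant}.
#' @export
geneAodSpearman <- function(resid, pheno, fdr_cut = 0.05) {
    h <- harmonizeSamples(resid, pheno)
    m <- .expr_matrix(h$x)
    if (ncol(m) < 3) stop("need at least 3 samples")
    aod <- h$pheno$aod
    const <- apply(m, 1, function(v) stats::sd(v) == 0)
    if (any(const))
        warning(sum(const), " constant gene(s) skipped: ",
                paste(utils::head(rownames(m)[const], 5), collapse = ", "))
    m <- m[!const, , drop = FALSE]
    st <- t(apply(m, 1, .spearman, b = aod))
    out <- data.frame(unit_a = rownames(m), unit_b = "AOD",
                      beta = st[, "rho"], p_value = st[, "p"],
                      fdr = stats::p.adjust(st[, "p"], "BH"),
                      row.names = NULL, stringsAsFactors = FALSE)
    out$significant <- out$fdr < fdr_cut
    out
}

#' Assemble candidate (CNV, gene, AOD) triplets
#'
#' A triplet is formed for every CNV-gene pair significant in the eQTL
#' scan whose CNV is significant in the CNV-AOD scan and whose gene is
#' significant in the gene-AOD screen; statistics from the three screens
#' are carried over. All three screens must have used the same trait
#' covariate.
#'
#' @param cnv_aod result of \code{\link{cnvAodScan}}.
#' @param cnv_gene result of \code{\link{cnvGeneScan}}.
#' @param gene_aod result of \code{\link{geneAodSpearman}}.
#' @return A data.frame per triplet: \code{cnv_id}, \code{gene_id},
#'   \code{beta_cnv_gene}, \code{fdr_cnv_gene}, \code{beta_cnv_aod},
#'   \code{fdr_cnv_aod}, \code{rho_gene_aod}, \code{fdr_gene_aod}.
#' @export
assembleTriplets <- function(cnv_aod, cnv_gene, gene_aod) {
    sig_cnv <- cnv_aod[cnv_aod$significant, , drop = FALSE]
    sig_pair <- cnv_gene[cnv_gene$significant, , drop = FALSE]
    sig_gene <- gene_aod[gene_aod$significant, , drop = FALSE]
    keep <- sig_pair$unit_a %in% sig_cnv$unit_a &
        sig_pair$unit_b %in% sig_gene$unit_a
    pair <- sig_pair[keep, , drop = FALSE]
    if (!nrow(pair))
        return(data.frame(cnv_id = character(), gene_id = character(),
                          beta_cnv_gene = numeric(),
                          fdr_cnv_gene = numeric(),
                          beta_cnv_aod = numeric(),
                          fdr_cnv_aod = numeric(),
                          rho_gene_aod = numeric(),
                          fdr_gene_aod = numeric(),
                          stringsAsFactors = FALSE))
    ia <- match(pair$unit_a, sig_cnv$unit_a)
    ig <- match(pair$unit_b, sig_gene$unit_a)
    out <- data.frame(cnv_id = pair$unit_a, gene_id = pair$unit_b,
                      beta_cnv_gene = pair$beta,
                      fdr_cnv_gene = pair$fdr,
                      beta_cnv_aod = sig_cnv$beta[ia],
                      fdr_cnv_aod = sig_cnv$fdr[ia],
                      rho_gene_aod = sig_gene$beta[ig],
                      fdr_gene_aod = sig_gene$fdr[ig],
                      stringsAsFactors = FALSE)
    ## deterministic order regardless of input row order
    out <- out[order(out$cnv_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
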