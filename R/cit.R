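#' Configuration for the Causal Inference Test
#'
#' @param n_perm permutation count for the conditional-independence
#'   component (default 1000; at least 100 is recommended for reported
#'   results).
#' @param alpha scenario-call threshold on the within-scenario FDR.
#' @param seed RNG seed driving the permutations.
#' @param adjust_covariates include the covariates in every component
#'   regression.
#' @return A list of class \code{"CITConfig"}.
#' @export
citConfig <- function(n_perm = 1000L, alpha = 0.05, seed = 1L,
                      adjust_covariates = TRUE) {
    stopifnot(n_perm >= 1, alpha > 0, alpha < 1)
    structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                   seed = as.integer(seed),
                   adjust_covariates = isTRUE(adjust_covariates)),
              class = "CITConfig")
}

## residual sum of squares of an OLS fit (no intercept column added)
.rss <- function(X, y) {
    f <- stats::.lm.fit(X, y)
    sum(f$residuals^2)
}

## partial F test for adding the single column `add` to design X0
.partial_f <- function(X0, add, y) {
    X1 <- cbind(X0, add)
    rss0 <- .rss(X0, y)
    rss1 <- .rss(X1, y)
    df2 <- length(y) - ncol(X1)
    f <- (rss0 - rss1) / (rss1 / df2)
    list(f = f, p = stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Component p-values of the Causal Inference Test
#'
#' For a candidate chain L -> G -> T (L an exposure such as CNV dosage,
#' G a putative mediator, T an outcome), computes the four component
#' tests of the CIT:
#' \enumerate{
#'   \item L and T are associated: F-test of L in \code{T ~ L}.
#'   \item L and G are associated given T: F-test of L in
#'     \code{G ~ T + L}.
#'   \item G and T are associated given L: F-test of G in
#'     \code{T ~ L + G}.
#'   \item T is independent of L given G: a permutation equivalence
#'     test. Fit \code{G ~ L}, build surrogate mediators
#'     \code{G*_b = fitted + permuted residuals}, compute the F
#'     statistic of L in \code{T ~ G*_b + L} for each permutation, and
#'     set \code{p4 = (1 + #\{F*_b <= F_obs\}) / (n_perm + 1)} where
#'     \code{F_obs} is the L statistic in \code{T ~ G + L}. Small
#'     \code{p4} means the observed residual L signal in T is as small
#'     as under full mediation.
#' }
#' Covariates, when supplied and enabled, enter every regression. The
#' chain is supported only when all four p-values are small; see
#' \code{\link{citOmnibus}}.
#'
#' @param L exposure vector (e.g. copy-number dosage; non-constant).
#' @param G mediator vector (non-constant).
#' @param T_ outcome vector.
#' @param covariates optional numeric matrix.
#' @param config a \code{\link{citConfig}}.
#' @return Named numeric vector \code{c(p1, p2, p3, p4)}.
#' @export
citComponents <- function(L, G, T_, covariates = NULL,
                          config = citConfig()) {
    stopifnot(inherits(config, "CITConfig"))
    n <- length(L)
    if (length(G) != n || length(T_) != n)
        stop("L, G and T must have equal length")
    if (n < 30)
        warning("fewer than 30 observations; CIT p-values are unstable")
    if (stats::sd(L) == 0) stop("constant L")
    if (stats::sd(G) == 0) stop("constant G")
    base <- matrix(1, n, 1)
    if (!is.null(covariates) && config$adjust_covariates) {
        covariates <- as.matrix(covariates)
        stopifnot(nrow(covariates) == n)
        base <- cbind(base, covariates)
    }
    p1 <- .partial_f(base, L, T_)$p
    p2 <- .partial_f(cbind(base, T_), L, G)$p
    p3 <- .partial_f(cbind(base, L), G, T_)$p

    ## p4: permutation equivalence test of T _||_ L | G
    set.seed(config$seed)
    fitG <- stats::.lm.fit(cbind(base, L), G)
    fitted_G <- G - fitG$residuals
    f_obs <- .partial_f(cbind(base, G), L, T_)$f
    f_star <- vapply(seq_len(config$n_perm), function(b) {
        g_star <- fitted_G + sample(fitG$residuals)
        .partial_f(cbind(base, g_star), L, T_)$f
    }, numeric(1))
    p4 <- (1 + sum(f_star <= f_obs)) / (config$n_perm + 1)
    c(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
}

#' Omnibus CIT p-value
#'
#' The intersection-union combination: the maximum of the four component
#' p-values, small only when every component condition holds.
#'
#' @param p numeric vector of the four component p-values (or four
#'   separate arguments).
#' @param ... further p-values when given separately.
#' @return \code{max(p1, p2, p3, p4)}.
#' @examples
#' citOmnibus(c(0.01, 0.02, 0.03, 0.04))
#' @export
citOmnibus <- function(p, ...) {
    p <- c(p, ...)
    if (length(p) != 4) stop("exactly four component p-values expected")
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    max(p)
}

#' Run the CIT in both causal directions and select the scenario
#'
#' For every triplet, the CIT is run twice: scenario 1 tests the chain
#' CNV -> gene -> AOD (gene expression as the mediator); scenario 2
#' tests CNV -> AOD -> gene (AOD as the mediator, i.e. aging drives the
#' expression change). Omnibus p-values are BH-adjusted within each
#' scenario across triplets, and the scenario with the more significant
#' FDR is called: \code{causal} when scenario 1 wins below \code{alpha},
#' \code{reactive} when scenario 2 wins, \code{ambiguous} on an exact
#' tie with both below \code{alpha}, otherwise \code{none}.
#'
#' @param triplets data.frame from \code{\link{assembleTriplets}}
#'   (columns \code{cnv_id}, \code{gene_id}); duplicated (cnv, gene)
#'   keys are collapsed.
#' @param x a \linkS4class{CNVDosage}.
#' @param expr_resid residualized expression
#'   (\code{SummarizedExperiment} or matrix).
#' @param pheno phenotype \code{DataFrame}.
#' @param trait pathology trait used as covariate (with sex).
#' @param config a \code{\link{citConfig}}.
#' @return A data.frame with one row per triplet x scenario: ids,
#'   \code{scenario}, \code{p1..p4}, \code{p_omni}, \code{fdr_omni} and
#'   the per-triplet \code{call}.
#' @export
scenarioSelect <- function(triplets, x, expr_resid, pheno,
                           trait = "cogdx", config = citConfig()) {
    stopifnot(inherits(config, "CITConfig"))
    if (!nrow(triplets)) {
        return(data.frame(cnv_id = character(), gene_id = character(),
                          scenario = integer(), p1 = numeric(),
                          p2 = numeric(), p3 = numeric(), p4 = numeric(),
                          p_omni = numeric(), fdr_omni = numeric(),
                          call = character(), stringsAsFactors = FALSE))
    }
    triplets <- triplets[!duplicated(triplets[c("cnv_id", "gene_id")]), ,
                         drop = FALSE]
    triplets <- triplets[order(triplets$cnv_id, triplets$gene_id), ,
                         drop = FALSE]
    m <- .expr_matrix(expr_resid)
    ids <- Reduce(intersect,
                  list(rownames(pheno), colnames(x), colnames(m)))
    ids <- rownames(pheno)[rownames(pheno) %in% ids]
    d <- dosage(x)[, ids, drop = FALSE]
    m <- m[, ids, drop = FALSE]
    ph <- pheno[ids, , drop = FALSE]
    cov <- .trait_design(ph, trait = .check_trait(trait))
    aod <- ph$aod
    nt <- nrow(triplets)
    run <- function(i, scen) {
        L <- as.numeric(d[triplets$cnv_id[i], ])
        g <- as.numeric(m[triplets$gene_id[i], ])
        cfg <- config
        ## per-triplet, per-scenario derived seed so each test has its own
        ## permutation stream (triplets are in deterministic sorted order)
        cfg$seed <- (config$seed + 7919L * i + 104729L * scen) %%
            .Machine$integer.max
        if (scen == 1L) citComponents(L, g, aod, cov, cfg)
        else citComponents(L, aod, g, cov, cfg)
    }
    res <- lapply(1:2, function(scen) {
        ps <- t(vapply(seq_len(nt), run, numeric(4), scen = scen))
        data.frame(cnv_id = triplets$cnv_id, gene_id = triplets$gene_id,
                   scenario = scen, ps,
                   p_omni = apply(ps, 1, max),
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    res[[1]]$fdr_omni <- stats::p.adjust(res[[1]]$p_omni, "BH")
    res[[2]]$fdr_omni <- stats::p.adjust(res[[2]]$p_omni, "BH")
    f1 <- res[[1]]$fdr_omni; f2 <- res[[2]]$fdr_omni
    call <- ifelse(f1 < f2 & f1 < config$alpha, "causal",
            ifelse(f2 < f1 & f2 < config$alpha, "reactive",
            ifelse(f1 == f2 & f1 < config$alpha, "ambiguous", "none")))
    res[[1]]$call <- call
    res[[2]]$call <- call
    out <- rbind(res[[1]], res[[2]])
    out <- out[order(out$cnv_id, out$gene_id, out$scenario), , drop = FALSE]
    rownames(out) <- NULL
    out
}
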