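#' @importFrom survival survfit survdiff Surv
NULL

#' Kaplan-Meier curves and log-rank test by copy-number dosage group
#'
#' Samples are grouped by their integer dosage at one CNV; groups with
#' fewer than \code{min_group} samples are merged into the nearest
#' dosage group (with a warning). Age of death is the time-to-event and
#' every subject is treated as an observed death unless an
#' \code{event} vector is supplied. Curves come from the product-limit
#' estimator (\code{survival::survfit}) and the K-group log-rank test
#' from \code{survival::survdiff}.
#'
#' @param dosage_row named integer vector of per-sample copy numbers
#'   (names = sample ids).
#' @param pheno phenotype \code{DataFrame} with \code{aod}.
#' @param event optional 0/1 event indicator per sample (default: all 1,
#'   i.e. no censoring).
#' @param min_group minimal group size before merging.
#' @return A list: \code{cnv_id}-free \code{groups} (dosage value per
#'   sample after merging), \code{km} (data.frame of per-group
#'   \code{time}, \code{surv}, \code{n_risk} steps),
#'   \code{logrank_chi2}, \code{logrank_df}, \code{logrank_p}.
#' @export
kmLogrank <- function(dosage_row, pheno, event = NULL, min_group = 2L) {
    ids <- intersect(rownames(pheno), names(dosage_row))
    if (!length(ids)) stop("no shared samples")
    dos <- dosage_row[ids]
    aod <- pheno[ids, "aod"]
    if (is.null(event)) event <- rep(1L, length(ids))
    tab <- table(dos)
    small <- as.integer(names(tab)[tab < min_group])
    if (length(small) && length(tab) > 1) {
        warning("merging dosage group(s) ",
                paste(small, collapse = ", "),
                " (n < ", min_group, ") into the nearest dosage group")
        keepv <- as.integer(names(tab)[tab >= min_group])
        if (!length(keepv))
            stop("no dosage group reaches the minimal size")
        for (s in small) {
            tgt <- keepv[which.min(abs(keepv - s))]
            dos[dos == s] <- tgt
        }
    }
    if (length(unique(dos)) < 2)
        stop("only one dosage group present; no survival comparison ",
             "possible")
    grp <- factor(dos)
    fit <- survival::survfit(survival::Surv(aod, event) ~ grp)
    strata <- rep(names(fit$strata), fit$strata)
    km <- data.frame(group = sub("^grp=", "", strata),
                     time = fit$time, surv = fit$surv,
                     n_risk = fit$n.risk, stringsAsFactors = FALSE)
    sd <- survival::survdiff(survival::Surv(aod, event) ~ grp)
    df <- length(sd$n) - 1
    list(groups = stats::setNames(as.integer(as.character(grp)), ids),
         km = km,
         logrank_chi2 = unname(sd$chisq),
         logrank_df = df,
         logrank_p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Gene-set over-representation by Fisher's exact test
#'
#' Per term, builds the 2x2 table of (in input set / not) x (in term /
#' not) over the supplied background universe and computes the one-sided
#' Fisher's exact (hypergeometric upper-tail) enrichment p-value, the
#' fold enrichment \code{(a / input) / (term / background)}, and a BH
#' FDR across terms. Terms are intersected with the background before
#' testing.
#'
#' @param input_genes character vector, must be a subset of
#'   \code{background}.
#' @param gene_sets named list of character vectors (e.g. from
#'   \code{\link{readGmt}}).
#' @param background the gene universe.
#' @return A data.frame per term: \code{term_name}, \code{a} (input in
#'   term), \code{b} (background-only in term), \code{c} (input not in
#'   term), \code{d} (rest), \code{fold_enrichment}, \code{p_value},
#'   \code{fdr}.
#' @export
fisherEnrichment <- function(input_genes, gene_sets, background) {
    input_genes <- unique(input_genes)
    background <- unique(background)
    off <- setdiff(input_genes, background)
    if (length(off))
        stop("input gene(s) absent from the background: ",
             paste(off, collapse = ", "))
    n <- length(background)
    ni <- length(input_genes)
    rows <- lapply(names(gene_sets), function(nm) {
        term <- intersect(unique(gene_sets[[nm]]), background)
        a <- length(intersect(input_genes, term))
        b <- length(term) - a
        c_ <- ni - a
        d <- n - a - b - c_
        ## upper-tail hypergeometric: P(X >= a)
        p <- if (a == 0) 1 else
            stats::phyper(a - 1, length(term), n - length(term), ni,
                          lower.tail = FALSE)
        fold <- if (length(term) == 0) 0 else
            (a / ni) / (length(term) / n)
        data.frame(term_name = nm, a = a, b = b, c = c_, d = d,
                   fold_enrichment = fold, p_value = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- stats::p.adjust(out$p_value, "BH")
    out
}

#' Export the CNV-gene-AOD network for Cytoscape
#'
#' In \code{correlation} mode every triplet contributes undirected
#' edges CNV-gene, gene-AOD and CNV-AOD, signed by the relevant beta or
#' Spearman rho. In \code{causality} mode only triplets whose CIT call
#' is \code{causal} (chain CNV -> gene -> AOD) or \code{reactive}
#' (CNV -> AOD -> gene) are kept and edges are directed along the called
#' chain. Files written: a SIF, a node-attribute TSV (\code{id},
#' \code{type}) and an edge-attribute TSV (\code{source}, \code{target},
#' \code{interaction}, \code{sign}, \code{weight}, \code{directed}).
#'
#' @param triplets data.frame from \code{\link{assembleTriplets}}.
#' @param cit CIT results from \code{\link{scenarioSelect}} (required
#'   for \code{mode = "causality"}).
#' @param mode \code{"correlation"} or \code{"causality"}.
#' @param prefix output path prefix; \code{<prefix>.sif},
#'   \code{<prefix>_nodes.tsv} and \code{<prefix>_edges.tsv} are
#'   written.
#' @return Invisibly, a list with the \code{nodes} and \code{edges}
#'   data frames and the written paths.
#' @export
exportNetwork <- function(triplets, cit = NULL,
                          mode = c("correlation", "causality"),
                          prefix) {
    mode <- match.arg(mode)
    tr <- triplets
    if (mode == "causality") {
        if (is.null(cit)) stop("causality mode needs CIT results")
        calls <- unique(cit[cit$call %in% c("causal", "reactive"),
                            c("cnv_id", "gene_id", "call")])
        tr <- merge(tr, calls, by = c("cnv_id", "gene_id"))
    }
    mk_edge <- function(src, tgt, inter, w, directed)
        data.frame(source = src, target = tgt, interaction = inter,
                   sign = ifelse(w < 0, "negative", "positive"),
                   weight = w, directed = directed,
                   stringsAsFactors = FALSE)
    edges <- NULL
    if (nrow(tr)) {
        if (mode == "correlation") {
            edges <- rbind(
                mk_edge(tr$cnv_id, tr$gene_id, "cnv-gene",
                        tr$beta_cnv_gene, FALSE),
                mk_edge(tr$gene_id, "AOD", "gene-aod",
                        tr$rho_gene_aod, FALSE),
                mk_edge(tr$cnv_id, "AOD", "cnv-aod",
                        tr$beta_cnv_aod, FALSE))
        } else {
            cz <- tr[tr$call == "causal", , drop = FALSE]
            rz <- tr[tr$call == "reactive", , drop = FALSE]
            edges <- rbind(
                if (nrow(cz)) mk_edge(cz$cnv_id, cz$gene_id, "cnv-gene",
                                      cz$beta_cnv_gene, TRUE),
                if (nrow(cz)) mk_edge(cz$gene_id, "AOD", "gene-aod",
                                      cz$rho_gene_aod, TRUE),
                if (nrow(rz)) mk_edge(rz$cnv_id, "AOD", "cnv-aod",
                                      rz$beta_cnv_aod, TRUE),
                if (nrow(rz)) mk_edge("AOD", rz$gene_id, "aod-gene",
                                      rz$rho_gene_aod, TRUE))
        }
        edges <- unique(edges)
    }
    if (is.null(edges))
        edges <- data.frame(source = character(), target = character(),
                            interaction = character(), sign = character(),
                            weight = numeric(), directed = logical(),
                            stringsAsFactors = FALSE)
    node_ids <- unique(c(edges$source, edges$target))
    nodes <- data.frame(
        id = node_ids,
        type = ifelse(node_ids == "AOD", "AOD",
               ifelse(node_ids %in% tr$gene_id, "gene", "CNV")),
        stringsAsFactors = FALSE)
    paths <- list(sif = paste0(prefix, ".sif"),
                  nodes = paste0(prefix, "_nodes.tsv"),
                  edges = paste0(prefix, "_edges.tsv"))
    writeLines(sprintf("%s\t%s\t%s", edges$source, edges$interaction,
                       edges$target), paths$sif)
    write.table(nodes, paths$nodes, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(edges, paths$edges, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(list(nodes = nodes, edges = edges, paths = paths))
}
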