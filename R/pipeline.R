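#' Pipeline configuration
#'
#' Either \code{sim} (a \code{\link{simConfig}}) or the three input
#' paths must be given. \code{trait} selects the pathology covariate for
#' the downstream stages; \code{"consensus"} runs the CNV-AOD scan under
#' all three traits and intersects the significant sets (downstream
#' stages then use cogdx, the primary clinical diagnosis).
#'
#' @param dosage_path,expression_path,phenotype_path input TSVs (ignored
#'   when \code{sim} is given; the simulated cohort is written into the
#'   output directory instead).
#' @param gene_sets_path optional GMT file for the enrichment stage (in
#'   simulation mode the generated collection is used by default).
#' @param sim optional \code{\link{simConfig}}; when present the cohort
#'   is simulated.
#' @param trait \code{"cogdx"}, \code{"braaksc"}, \code{"ceradsc"} or
#'   \code{"consensus"}.
#' @param fdr_cut,lfc_cut,overlap_cut thresholds (FDR 0.05, |logFC| 1,
#'   reciprocal overlap 0.5).
#' @param cit a \code{\link{citConfig}}; its seed is re-derived from
#'   \code{seed}.
#' @param outdir output directory.
#' @param seed top-level seed, fanned out deterministically to the
#'   stages.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(dosage_path = NULL, expression_path = NULL,
                           phenotype_path = NULL, gene_sets_path = NULL,
                           sim = NULL, trait = "consensus",
                           fdr_cut = 0.05, lfc_cut = 1,
                           overlap_cut = 0.5, cit = citConfig(),
                           outdir, seed = 1L) {
    stopifnot(trait %in% c(TRAIT_NAMES, "consensus"),
              fdr_cut > 0, lfc_cut > 0, overlap_cut > 0,
              inherits(cit, "CITConfig"))
    if (is.null(sim) &&
        (is.null(dosage_path) || is.null(expression_path) ||
         is.null(phenotype_path)))
        stop("either 'sim' or all three input paths must be supplied")
    structure(list(dosage_path = dosage_path,
                   expression_path = expression_path,
                   phenotype_path = phenotype_path,
                   gene_sets_path = gene_sets_path,
                   sim = sim, trait = trait, fdr_cut = fdr_cut,
                   lfc_cut = lfc_cut, overlap_cut = overlap_cut,
                   cit = cit, outdir = outdir, seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{pipelineConfig}};
#' a \code{sim:} block holds \code{\link{simConfig}} fields and a
#' \code{cit:} block \code{\link{citConfig}} fields.
#'
#' @param path YAML file.
#' @param outdir,seed overrides for the file's values (optional).
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path, outdir = NULL, seed = NULL) {
    y <- yaml::read_yaml(path)
    sim <- if (!is.null(y$sim)) do.call(simConfig, y$sim) else NULL
    cit <- if (!is.null(y$cit)) do.call(citConfig, y$cit) else citConfig()
    pipelineConfig(
        dosage_path = y$dosage_path, expression_path = y$expression_path,
        phenotype_path = y$phenotype_path,
        gene_sets_path = y$gene_sets_path,
        sim = sim, trait = if (is.null(y$trait)) "consensus" else y$trait,
        fdr_cut = if (is.null(y$fdr_cut)) 0.05 else y$fdr_cut,
        lfc_cut = if (is.null(y$lfc_cut)) 1 else y$lfc_cut,
        overlap_cut = if (is.null(y$overlap_cut)) 0.5 else y$overlap_cut,
        cit = cit,
        outdir = if (!is.null(outdir)) outdir else y$outdir,
        seed = if (!is.null(seed)) seed else
            if (is.null(y$seed)) 1L else y$seed)
}

.write_tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full CNV-gene-AOD causality pipeline
#'
#' Executes, in order: cohort loading (or simulation), frequency
#' summary, AD-vs-NL carrier frequency tests, per-trait CNV-AOD scans,
#' consensus CNV selection, severity residualization, eQTL scan on the
#' consensus CNVs, gene-AOD Spearman screen, triplet assembly, CIT
#' scenario selection, network export (correlation and causality),
#' per-CNV survival analysis, gene-set enrichment of the causal genes,
#' and a run manifest. Every stage is a pure function of (inputs,
#' config, seed): re-running with the same config reproduces every file
#' byte-identically. A stage failure aborts with the stage name; files
#' already written are left in place.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose log one line per stage with row counts.
#' @return The output directory, invisibly; see the manifest
#'   (\code{manifest.json}) for the artifact list.
#' @export
runPipeline <- function(config, verbose = TRUE) {
    stopifnot(inherits(config, "PipelineConfig"))
    out <- config$outdir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    log <- function(stage, fmt, ...) if (verbose)
        message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    artifacts <- character()
    add <- function(name, path) {
        artifacts[[name]] <<- basename(path)
        path
    }

    ## ---- load or simulate the cohort ----
    gene_sets <- NULL
    if (!is.null(config$sim)) {
        sim_cfg <- config$sim
        sim_cfg$seed <- config$seed
        paths <- stage("simulate", simulateCohortFiles(sim_cfg, out))
        dos <- stage("load", readDosageMatrix(paths$dosage,
                                              verbose = FALSE))
        expr <- readExpressionMatrix(paths$expression, verbose = FALSE)
        pheno <- readPhenotypes(paths$phenotypes)
        gene_sets <- readGmt(paths$gene_sets)
    } else {
        dos <- stage("load", readDosageMatrix(config$dosage_path,
                                              verbose = FALSE))
        expr <- readExpressionMatrix(config$expression_path,
                                     verbose = FALSE)
        pheno <- readPhenotypes(config$phenotype_path)
    }
    if (!is.null(config$gene_sets_path))
        gene_sets <- readGmt(config$gene_sets_path)
    log("load", "%d CNVs, %d genes, %d samples", nrow(dos), nrow(expr),
        nrow(pheno))

    ## ---- frequencies ----
    freq <- stage("frequency", summarizeFrequencies(dos))
    add("frequency_summary",
        .write_tsv(freq, file.path(out, "frequency_summary.tsv")))
    gft <- stage("group_frequency", groupFrequencyTest(dos, pheno))
    add("group_frequency_test",
        .write_tsv(gft, file.path(out, "group_frequency_test.tsv")))

    ## ---- per-trait CNV-AOD scans and consensus ----
    scan_traits <- if (config$trait == "consensus") TRAIT_NAMES
        else config$trait
    scans <- stage("cnv_aod", lapply(scan_traits, function(tr)
        cnvAodScan(dos, pheno, trait = tr, fdr_cut = config$fdr_cut)))
    names(scans) <- scan_traits
    add("cnv_aod_results",
        .write_tsv(do.call(rbind, scans),
                   file.path(out, "cnv_aod_results.tsv")))
    sig_sets <- lapply(scans, function(s) s$unit_a[s$significant])
    consensus <- if (config$trait == "consensus")
        consensusAcrossTraits(sig_sets) else sig_sets[[config$trait]]
    consensus <- sort(consensus)
    add("consensus_cnvs",
        .write_tsv(data.frame(cnv_id = consensus),
                   file.path(out, "consensus_cnvs.tsv")))
    log("cnv_aod", "%s -> %d consensus CNVs",
        paste(vapply(sig_sets, length, 1L), collapse = "/"),
        length(consensus))

    down_trait <- if (config$trait == "consensus") "cogdx" else
        config$trait

    ## ---- expression residualization and gene-AOD screen ----
    resid <- stage("residualize", residualize(expr, pheno, down_trait))
    gene_aod <- stage("gene_aod",
                      geneAodSpearman(resid, pheno,
                                      fdr_cut = config$fdr_cut))
    add("gene_aod_results",
        .write_tsv(gene_aod, file.path(out, "gene_aod_results.tsv")))
    log("gene_aod", "%d/%d genes significant",
        sum(gene_aod$significant), nrow(gene_aod))

    ## ---- eQTL scan on consensus CNVs ----
    if (length(consensus)) {
        pairs <- stage("cnv_gene",
                       cnvGeneScan(dos[consensus, ], expr, pheno,
                                   trait = down_trait,
                                   fdr_cut = config$fdr_cut))
    } else {
        pairs <- data.frame(unit_a = character(), unit_b = character(),
                            beta = numeric(), se = numeric(),
                            t_stat = numeric(), p_value = numeric(),
                            fdr = numeric(), trait_covariate = character(),
                            significant = logical())
    }
    add("cnv_gene_pairs",
        .write_tsv(pairs, file.path(out, "cnv_gene_pairs.tsv")))
    log("cnv_gene", "%d/%d pairs significant",
        sum(pairs$significant), nrow(pairs))

    ## ---- triplets and CIT ----
    trip <- stage("triplets",
                  assembleTriplets(scans[[down_trait]], pairs, gene_aod))
    add("triplets", .write_tsv(trip, file.path(out, "triplets.tsv")))
    cit_cfg <- config$cit
    cit_cfg$seed <- (config$seed + 5077L) %% .Machine$integer.max
    cit <- stage("cit", scenarioSelect(trip, dos, resid, pheno,
                                       trait = down_trait,
                                       config = cit_cfg))
    add("cit_report", .write_tsv(cit, file.path(out, "cit_report.tsv")))
    log("cit", "%d triplets, %d causal calls", nrow(trip),
        sum(cit$call == "causal" & cit$scenario == 1))

    ## ---- networks ----
    stage("network", {
        exportNetwork(trip, cit, "correlation",
                      file.path(out, "correlation_network"))
        exportNetwork(trip, cit, "causality",
                      file.path(out, "causality_network"))
    })
    add("causality_network", file.path(out, "causality_network.sif"))

    ## ---- survival by dosage group for consensus CNVs ----
    surv <- stage("survival", {
        rows <- lapply(consensus, function(cv) {
            r <- tryCatch(
                suppressWarnings(
                    kmLogrank(dosage(dos)[cv, ], pheno)),
                error = function(e) NULL)
            if (is.null(r))
                data.frame(cnv_id = cv, n_groups = NA_integer_,
                           logrank_chi2 = NA_real_,
                           logrank_df = NA_integer_,
                           logrank_p = NA_real_)
            else
                data.frame(cnv_id = cv,
                           n_groups = length(unique(r$groups)),
                           logrank_chi2 = r$logrank_chi2,
                           logrank_df = r$logrank_df,
                           logrank_p = r$logrank_p)
        })
        if (length(rows)) do.call(rbind, rows)
        else data.frame(cnv_id = character(), n_groups = integer(),
                        logrank_chi2 = numeric(), logrank_df = integer(),
                        logrank_p = numeric())
    })
    add("survival_report",
        .write_tsv(surv, file.path(out, "survival_report.tsv")))

    ## ---- enrichment of causal genes ----
    causal_genes <- sort(unique(
        cit$gene_id[cit$call == "causal" & cit$scenario == 1]))
    enr <- if (!is.null(gene_sets) && length(causal_genes)) {
        stage("enrichment",
              fisherEnrichment(causal_genes, gene_sets, rownames(expr)))
    } else {
        data.frame(term_name = character(), a = integer(), b = integer(),
                   c = integer(), d = integer(),
                   fold_enrichment = numeric(), p_value = numeric(),
                   fdr = numeric())
    }
    add("enrichment_report",
        .write_tsv(enr, file.path(out, "enrichment_report.tsv")))

    ## ---- manifest ----
    manifest <- list(
        package = "cnvLongevity",
        version = as.character(utils::packageVersion("cnvLongevity")),
        seed = config$seed,
        trait = config$trait,
        thresholds = list(fdr = config$fdr_cut, logfc = config$lfc_cut,
                          overlap = config$overlap_cut),
        cit = list(n_perm = cit_cfg$n_perm, alpha = cit_cfg$alpha),
        simulated = !is.null(config$sim),
        artifacts = as.list(artifacts))
    manifest$artifacts$manifest <- "manifest.json"
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    log("done", "%d artifacts in %s", length(manifest$artifacts), out)
    invisible(out)
}
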