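#' Simulation configuration for a synthetic aging cohort
#'
#' Bundles and validates the parameters of \code{\link{generateCohort}}.
#' Defaults emulate the cohort structure the analysis targets: ~1,100
#' diploid individuals, rare CNVs (allele frequencies around 0.1-1.25%),
#' log2-scale expression with CNV- and severity-driven components, and an
#' age-of-death (AOD) phenotype capped at 90 years.
#'
#' @param n_samples number of individuals.
#' @param n_cnvs number of CNV loci.
#' @param n_genes number of genes.
#' @param allele_freq_range range (pair of fractions in (0, 0.5)) from
#'   which each CNV's deviant-allele frequency is drawn.
#' @param frac_causal_cnvs fraction of CNVs given true mediated
#'   (CNV -> gene -> AOD) effects.
#' @param frac_reactive_cnvs fraction of CNVs given true reactive
#'   (CNV -> AOD -> gene) structure.
#' @param genes_per_causal_cnv mediator (or reactive) genes per such CNV.
#' @param beta_cg effect of one dosage unit on mediator expression
#'   (log2 units per copy).
#' @param beta_ga effect of one expression unit on AOD (years per log2
#'   unit).
#' @param beta_direct direct CNV -> AOD effect for reactive CNVs (years
#'   per copy).
#' @param beta_ag AOD -> expression slope for reactive genes (log2 units
#'   per year).
#' @param sd_expr residual expression SD (log2 units).
#' @param sd_aod residual AOD SD (years).
#' @param aod_mean mean age of death before capping (years).
#' @param aod_cap cap applied to generated AOD (years).
#' @param seed RNG seed.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_samples = 1100L, n_cnvs = 200L, n_genes = 2000L,
                      allele_freq_range = c(0.004, 0.0125),
                      frac_causal_cnvs = 0.015, frac_reactive_cnvs = 0.01,
                      genes_per_causal_cnv = 1L,
                      beta_cg = 1.5, beta_ga = 8, beta_direct = 8,
                      beta_ag = 0.1,
                      sd_expr = 0.5, sd_aod = 8,
                      aod_mean = 83, aod_cap = 90, seed = 1L) {
    cfg <- list(n_samples = as.integer(n_samples),
                n_cnvs = as.integer(n_cnvs), n_genes = as.integer(n_genes),
                allele_freq_range = as.numeric(allele_freq_range),
                frac_causal_cnvs = frac_causal_cnvs,
                frac_reactive_cnvs = frac_reactive_cnvs,
                genes_per_causal_cnv = as.integer(genes_per_causal_cnv),
                beta_cg = beta_cg, beta_ga = beta_ga,
                beta_direct = beta_direct, beta_ag = beta_ag,
                sd_expr = sd_expr, sd_aod = sd_aod,
                aod_mean = aod_mean, aod_cap = aod_cap,
                seed = as.integer(seed))
    stopifnot(cfg$n_samples > 0, cfg$n_cnvs > 0, cfg$n_genes > 0,
              length(cfg$allele_freq_range) == 2,
              all(cfg$allele_freq_range > 0),
              all(cfg$allele_freq_range < 0.5),
              cfg$frac_causal_cnvs >= 0, cfg$frac_causal_cnvs < 1,
              cfg$frac_reactive_cnvs >= 0, cfg$frac_reactive_cnvs < 1,
              cfg$frac_causal_cnvs + cfg$frac_reactive_cnvs < 1,
              cfg$genes_per_causal_cnv > 0,
              cfg$sd_expr > 0, cfg$sd_aod > 0)
    class(cfg) <- "SimConfig"
    cfg
}

## Latent disease-severity scale shared by the three pathology scores.
## Scores are noisy monotone transforms: correlated but not identical.
.sim_pathology <- function(n, severity) {
    noisy <- function(sd) severity + stats::rnorm(n, 0, sd)
    q1 <- stats::pnorm(noisy(0.8), sd = sqrt(1 + 0.64))
    ## ~32% normal cognition, remainder spread over diagnoses 2-5
    cogdx <- findInterval(q1, c(0.32, 0.50, 0.65, 0.85)) + 1L
    q2 <- stats::pnorm(noisy(0.8), sd = sqrt(1 + 0.64))
    braaksc <- findInterval(q2, c(0.05, 0.15, 0.35, 0.60, 0.80, 0.95))
    q3 <- stats::pnorm(noisy(0.8), sd = sqrt(1 + 0.64))
    ceradsc <- findInterval(q3, c(0.30, 0.50, 0.70)) + 1L
    list(cogdx = as.integer(cogdx), braaksc = as.integer(braaksc),
         ceradsc = as.integer(ceradsc))
}

#' Generate a synthetic cohort with known mediation ground truth
#'
#' Draws, per CNV, integer copy-number dosages as binomial(2, AF)
#' deviations around the diploid baseline 2, with deviation direction set
#' by CNV type (DEL loci lose copies, DUP loci gain, mCNV loci mix).
#' Expression is log2-scale with a gene-specific baseline, a
#' disease-severity component and Gaussian noise; mediator genes of
#' causal CNVs add \code{beta_cg * (dosage - 2)}. AOD is built as
#' \code{aod_mean} plus mediated expression effects (\code{beta_ga} per
#' log2 unit), direct effects of reactive CNVs, sex and severity effects
#' and Gaussian noise, then capped at \code{aod_cap}. Reactive genes are
#' generated from the capped AOD (\code{beta_ag} per year), mirroring the
#' reactive causal scenario. Identical config (including seed) gives
#' bit-identical output.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A list with elements \code{dosage} (\linkS4class{CNVDosage}),
#'   \code{expr} (\code{SummarizedExperiment}, assay \code{"log2expr"}),
#'   \code{pheno} (phenotype \code{DataFrame}) and \code{truth} (list with
#'   \code{causal_edges} and \code{reactive_edges} data frames carrying the
#'   true effect sizes; every (cnv, gene) pair absent from both lists is a
#'   null pair).
#' @export
generateCohort <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimConfig"))
    n_causal <- round(config$frac_causal_cnvs * config$n_cnvs)
    n_react <- round(config$frac_reactive_cnvs * config$n_cnvs)
    need_genes <- (n_causal + n_react) * config$genes_per_causal_cnv
    if (need_genes > config$n_genes)
        stop("config implies more causal/reactive gene assignments (",
             need_genes, ") than genes (", config$n_genes, ")")
    set.seed(config$seed)
    n <- config$n_samples
    samples <- sprintf("S%05d", seq_len(n))
    genes <- sprintf("G%05d", seq_len(config$n_genes))

    ## ---- CNV loci ----
    type <- sample(c("DEL", "DUP", "mCNV"), config$n_cnvs, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
    cnv_ids <- sprintf("%s%04d", type, seq_len(config$n_cnvs))
    af <- stats::runif(config$n_cnvs, config$allele_freq_range[1],
                       config$allele_freq_range[2])
    chrom <- paste0("chr", sample(1:22, config$n_cnvs, replace = TRUE))
    width <- as.integer(round(stats::runif(config$n_cnvs, 1e3, 1e5)))
    start <- as.integer(round(stats::runif(config$n_cnvs, 1e6, 2e8)))

    dos <- matrix(2L, config$n_cnvs, n, dimnames = list(cnv_ids, samples))
    for (i in seq_len(config$n_cnvs)) {
        alleles <- stats::rbinom(n, 2, af[i])
        if (type[i] == "DEL") dev <- -alleles
        else if (type[i] == "DUP") dev <- alleles
        else {
            dels <- stats::rbinom(n, alleles, 0.5)
            dev <- (alleles - dels) - dels
        }
        dos[i, ] <- 2L + as.integer(dev)
    }

    ## ---- phenotype covariates ----
    severity <- stats::rnorm(n)
    sex <- stats::rbinom(n, 1, 0.5)
    path <- .sim_pathology(n, severity)

    ## ---- edge assignment ----
    causal_cnvs <- if (n_causal) sample(cnv_ids, n_causal) else character()
    react_cnvs <- if (n_react)
        sample(setdiff(cnv_ids, causal_cnvs), n_react) else character()
    gene_pool <- sample(genes, need_genes)
    k <- config$genes_per_causal_cnv
    causal_edges <- data.frame(
        cnv_id = rep(causal_cnvs, each = k),
        gene_id = gene_pool[seq_len(n_causal * k)],
        beta_cg = rep(config$beta_cg, n_causal * k),
        beta_ga = rep(config$beta_ga, n_causal * k),
        stringsAsFactors = FALSE)
    reactive_edges <- data.frame(
        cnv_id = rep(react_cnvs, each = k),
        gene_id = gene_pool[n_causal * k + seq_len(n_react * k)],
        beta_direct = rep(config$beta_direct, n_react * k),
        beta_ag = rep(config$beta_ag, n_react * k),
        stringsAsFactors = FALSE)

    ## ---- expression: baseline + severity loading + noise ----
    baseline <- stats::rnorm(config$n_genes, 6, 1)
    sev_load <- stats::rnorm(config$n_genes, 0, 0.3)
    expr <- baseline +
        outer(sev_load, severity) +
        matrix(stats::rnorm(config$n_genes * n, 0, config$sd_expr),
               config$n_genes, n)
    dimnames(expr) <- list(genes, samples)
    for (e in seq_len(nrow(causal_edges))) {
        g <- causal_edges$gene_id[e]
        cv <- causal_edges$cnv_id[e]
        expr[g, ] <- expr[g, ] + config$beta_cg * (dos[cv, ] - 2)
    }

    ## ---- AOD: mediated + direct + covariate effects, then cap ----
    aod <- config$aod_mean - 1.5 * sex - 2.0 * severity +
        stats::rnorm(n, 0, config$sd_aod)
    for (e in seq_len(nrow(causal_edges))) {
        g <- causal_edges$gene_id[e]
        ## the mediator channels its dosage-driven component and its own
        ## intrinsic noise into AOD; the severity component of expression
        ## is excluded so severity confounds AOD only via its direct term
        ## (otherwise beta_ga would amplify a random severity->AOD
        ## coefficient per cohort)
        gi <- match(g, genes)
        aod <- aod + config$beta_ga *
            (expr[g, ] - baseline[gi] - sev_load[gi] * severity)
    }
    for (cv in react_cnvs)
        aod <- aod + config$beta_direct * (dos[cv, ] - 2)
    aod <- pmin(aod, config$aod_cap)

    ## reactive genes respond to the (capped) realized AOD
    for (e in seq_len(nrow(reactive_edges))) {
        g <- reactive_edges$gene_id[e]
        expr[g, ] <- expr[g, ] + config$beta_ag * (aod - config$aod_mean)
    }

    pheno <- S4Vectors::DataFrame(
        aod = aod, sex = as.integer(sex), cogdx = path$cogdx,
        braaksc = path$braaksc, ceradsc = path$ceradsc,
        group = ifelse(path$cogdx == 1L, "NL", "AD"),
        row.names = samples)

    list(dosage = CNVDosage(dos, chrom = chrom, start = start,
                            end = start + width - 1L, cnv_type = type),
         expr = SummarizedExperiment::SummarizedExperiment(
             assays = list(log2expr = expr)),
         pheno = pheno,
         truth = list(causal_edges = causal_edges,
                      reactive_edges = reactive_edges))
}

#' Generate a synthetic external CNV database for overlap validation
#'
#' For a configurable subset of the query CNVs emits a jittered copy (same
#' type, reciprocal overlap guaranteed > 50%); for the rest emits decoys
#' (wrong type at the same span, or a shifted copy with reciprocal overlap
#' <= 50%). The returned table labels which records are intended matches,
#' so overlap-validation sensitivity/specificity can be checked against
#' known truth. Coordinates are 1-based, closed, as in the query.
#'
#' @param dosage a \linkS4class{CNVDosage} whose CNV records to mirror.
#' @param match_fraction fraction of query CNVs given a true match.
#' @param jitter_frac maximal shift of a true match, as a fraction of the
#'   record width; must be < 0.5 so reciprocal overlap stays > 50%.
#' @param seed RNG seed.
#' @return A data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{type}, \code{source_id}, \code{query_id},
#'   \code{intended_match}.
#' @export
generateExternalCnvDb <- function(dosage, match_fraction = 0.7,
                                  jitter_frac = 0.2, seed = 1L) {
    stopifnot(nrow(dosage) > 0, jitter_frac >= 0, jitter_frac < 0.5,
              match_fraction >= 0, match_fraction <= 1)
    set.seed(seed)
    rr <- SummarizedExperiment::rowRanges(dosage)
    n <- length(rr)
    is_match <- seq_len(n) %in% sample(n, round(match_fraction * n))
    w <- GenomicRanges::width(rr)
    st <- GenomicRanges::start(rr)
    type <- cnvType(dosage)
    out_start <- integer(n); out_type <- character(n)
    for (i in seq_len(n)) {
        if (is_match[i]) {
            shift <- round(jitter_frac * w[i] *
                           stats::runif(1, -1, 1))
            out_start[i] <- st[i] + shift
            out_type[i] <- type[i]
        } else if (type[i] %in% c("DEL", "DUP")) {
            ## decoy: same span, opposite type
            out_start[i] <- st[i]
            out_type[i] <- if (type[i] == "DEL") "DUP" else "DEL"
        } else {
            ## mCNV matches any type, so the decoy must fail on overlap
            out_start[i] <- st[i] + as.integer(ceiling(0.75 * w[i]))
            out_type[i] <- type[i]
        }
    }
    data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
               start = out_start, end = out_start + w - 1L,
               type = out_type,
               source_id = sprintf("EXT%04d", seq_len(n)),
               query_id = names(rr),
               intended_match = is_match,
               stringsAsFactors = FALSE)
}

#' Generate a GMT-style gene-set collection with one spiked set
#'
#' @param genes the gene universe.
#' @param spiked_genes genes to enrich in the spiked set; a configurable
#'   number of them (\code{spike_count}) is placed into a set of size
#'   \code{set_size}, the remainder of which is drawn at random.
#' @param n_random number of additional purely random sets.
#' @param set_size size of every set.
#' @param spike_count how many of \code{spiked_genes} the spiked set holds
#'   (default: all of them, capped at \code{set_size}).
#' @param seed RNG seed.
#' @return A named list of character vectors; the spiked set is named
#'   \code{"SPIKED_SET"}. Write with \code{\link{writeGmt}}.
#' @export
generateGeneSets <- function(genes, spiked_genes = character(),
                             n_random = 10L, set_size = 50L,
                             spike_count = NULL, seed = 1L) {
    stopifnot(length(genes) >= 2)
    if (set_size > length(genes))
        stop("requested set size (", set_size,
             ") exceeds the gene universe (", length(genes), ")")
    set.seed(seed)
    sets <- list()
    if (length(spiked_genes)) {
        if (is.null(spike_count))
            spike_count <- min(length(spiked_genes), set_size)
        sp <- spiked_genes[seq_len(spike_count)]
        filler <- sample(setdiff(genes, sp), set_size - length(sp))
        sets$SPIKED_SET <- c(sp, filler)
    }
    for (i in seq_len(n_random))
        sets[[sprintf("RANDOM_SET_%03d", i)]] <- sample(genes, set_size)
    sets
}

#' Write / read GMT gene-set files
#'
#' GMT is tab-separated: term, description, then member genes.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @return \code{path} (write) or a named list (read).
#' @export
writeGmt <- function(sets, path) {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-c(1, 2)])
    names(sets) <- vapply(parts, `[`, character(1), 1)
    sets
}

#' Write a full synthetic cohort to disk
#'
#' Writes the three cohort TSVs, a BED-like external CNV set, a GMT
#' gene-set collection (spiked with the true mediator genes) and a
#' ground-truth edge TSV into \code{outdir}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param outdir output directory (created if absent).
#' @return Invisibly, the list of file paths written.
#' @export
simulateCohortFiles <- function(config = simConfig(), outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    coh <- generateCohort(config)
    paths <- list(
        dosage = file.path(outdir, "dosage.tsv"),
        expression = file.path(outdir, "expression.tsv"),
        phenotypes = file.path(outdir, "phenotypes.tsv"),
        external_db = file.path(outdir, "external_cnv_db.tsv"),
        gene_sets = file.path(outdir, "gene_sets.gmt"),
        ground_truth = file.path(outdir, "ground_truth.tsv"))
    writeDosageMatrix(coh$dosage, paths$dosage)
    writeExpressionMatrix(coh$expr, paths$expression)
    writePhenotypes(coh$pheno, paths$phenotypes)
    db <- generateExternalCnvDb(coh$dosage, seed = config$seed + 101L)
    write.table(db, paths$external_db, sep = "\t", quote = FALSE,
                row.names = FALSE)
    sets <- generateGeneSets(rownames(coh$expr),
                             spiked_genes = coh$truth$causal_edges$gene_id,
                             seed = config$seed + 202L)
    writeGmt(sets, paths$gene_sets)
    tr <- rbind(
        if (nrow(coh$truth$causal_edges))
            data.frame(coh$truth$causal_edges[, c("cnv_id", "gene_id")],
                       role = "causal"),
        if (nrow(coh$truth$reactive_edges))
            data.frame(coh$truth$reactive_edges[, c("cnv_id", "gene_id")],
                       role = "reactive"))
    if (is.null(tr))
        tr <- data.frame(cnv_id = character(), gene_id = character(),
                         role = character())
    write.table(tr, paths$ground_truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(paths)
}
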