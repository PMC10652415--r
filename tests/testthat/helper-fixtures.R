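## Shared in-code fixtures for the test suite (no stored data files).

## tiny dosage object: `dos` is a CNVs x samples integer matrix
make_dosage <- function(dos, types = NULL) {
    n <- nrow(dos)
    if (is.null(types)) types <- rep("DEL", n)
    CNVDosage(dos,
              chrom = rep("chr1", n),
              start = seq(1000, by = 10000, length.out = n),
              end = seq(1000, by = 10000, length.out = n) + 999,
              cnv_type = types)
}

## dosage object with a prescribed number of deletion / duplication
## carriers (one deviant allele per carrier) among n samples
make_carrier_dosage <- function(cnv_ids, n_del, n_dup, n_samples,
                                types = NULL) {
    k <- length(cnv_ids)
    m <- matrix(2L, k, n_samples,
                dimnames = list(cnv_ids,
                                sprintf("S%04d", seq_len(n_samples))))
    for (i in seq_len(k)) {
        if (n_del[i] > 0) m[i, seq_len(n_del[i])] <- 1L
        if (n_dup[i] > 0) m[i, n_del[i] + seq_len(n_dup[i])] <- 3L
    }
    if (is.null(types))
        types <- ifelse(n_del > 0 & n_dup > 0, "mCNV",
                 ifelse(n_dup > 0, "DUP", "DEL"))
    make_dosage(m, types)
}

## minimal phenotype DataFrame
make_pheno <- function(n, aod = NULL, sex = NULL, cogdx = NULL,
                       seed = 42) {
    set.seed(seed)
    if (is.null(aod)) aod <- pmin(rnorm(n, 85, 6), 90)
    if (is.null(sex)) sex <- rbinom(n, 1, 0.5)
    if (is.null(cogdx)) cogdx <- sample(1:5, n, replace = TRUE)
    S4Vectors::DataFrame(
        aod = aod, sex = as.integer(sex), cogdx = as.integer(cogdx),
        braaksc = as.integer(sample(0:6, n, replace = TRUE)),
        ceradsc = as.integer(sample(1:4, n, replace = TRUE)),
        group = ifelse(cogdx == 1, "NL", "AD"),
        row.names = sprintf("S%04d", seq_len(n)))
}

## write a dosage TSV from raw character cells (to exercise parse errors)
write_raw_dosage_tsv <- function(path, cells,
                                 samples = paste0("s", seq_along(cells))) {
    header <- paste(c("cnv_id", "chrom", "start", "end", "cnv_type",
                      samples), collapse = "\t")
    row <- paste(c("DEL0001", "chr1", "100", "200", "DEL", cells),
                 collapse = "\t")
    writeLines(c(header, row), path)
    path
}
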