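test_that("frequency arithmetic follows allele counting rules", {
    ## two deletion carriers among 1,127 samples
    d <- make_carrier_dosage("DEL0001", 2, 0, 1127)
    fs <- summarizeFrequencies(d)
    expect_equal(fs$allele_count_total, 2)
    expect_equal(fs$allele_number, 2254)
    expect_equal(fs$allele_frequency, 2 / 2254)
    expect_equal(round(100 * fs$allele_frequency, 4), 0.0887)
    expect_equal(fs$carrier_count, 2)
    expect_equal(round(100 * fs$carrier_frequency, 2), 0.18)

    ## all samples diploid
    d0 <- make_dosage(matrix(2L, 1, 10,
                             dimnames = list("DEL0002", paste0("s", 1:10))))
    fs0 <- summarizeFrequencies(d0)
    expect_equal(fs0$allele_count_total, 0)
    expect_equal(fs0$allele_frequency, 0)
    expect_equal(fs0$carrier_count, 0)

    ## homozygous deletion counts two alleles from one carrier
    d2 <- make_dosage(matrix(c(0L, 2L, 2L), 1, 3,
                             dimnames = list("DEL0003", paste0("s", 1:3))))
    fs2 <- summarizeFrequencies(d2)
    expect_equal(fs2$allele_count_del, 2)
    expect_equal(fs2$carrier_count, 1)
})

test_that("frequency invariants hold on random dosage matrices", {
    set.seed(13)
    for (rep in 1:5) {
        m <- matrix(sample(0:4, 200, replace = TRUE,
                           prob = c(.02, .08, .8, .08, .02)),
                    4, 50, dimnames = list(paste0("CNV", 1:4),
                                           paste0("s", 1:50)))
        fs <- summarizeFrequencies(make_dosage(m, rep("mCNV", 4)))
        expect_equal(fs$allele_count_total,
                     fs$allele_count_del + fs$allele_count_dup)
        expect_equal(fs$allele_frequency,
                     fs$allele_count_total / fs$allele_number)
        expect_true(all(fs$carrier_count <= fs$allele_count_total))
        expect_true(all(fs$carrier_frequency >= 0 &
                        fs$carrier_frequency <= 1))
    }
})

test_that("group frequency chi-square matches the closed form", {
    ## perfect independence
    d <- make_carrier_dosage("DEL0001", 20, 0, 40)
    pheno <- make_pheno(40, cogdx = rep(c(1, 4, 1, 4), 10))
    gt <- groupFrequencyTest(d, pheno)
    expect_equal(gt$chi2, 0, tolerance = 1e-12)
    expect_equal(gt$p_value, 1, tolerance = 1e-12)

    ## closed-form oracle on random 2x2 tables with positive expecteds
    chi2_oracle <- function(tab) {
        E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        sum((tab - E)^2 / E)
    }
    set.seed(29)
    for (rep in 1:10) {
        nAD <- sample(20:60, 1); nNL <- sample(20:60, 1)
        cAD <- sample(5:15, 1); cNL <- sample(5:15, 1)
        cogdx <- c(rep(4, nAD), rep(1, nNL))
        dos <- matrix(2L, 1, nAD + nNL,
                      dimnames = list("DEL0001",
                                      sprintf("S%04d", 1:(nAD + nNL))))
        dos[1, c(seq_len(cAD), nAD + seq_len(cNL))] <- 1L
        gt <- groupFrequencyTest(make_dosage(dos),
                                 make_pheno(nAD + nNL, cogdx = cogdx))
        tab <- matrix(c(gt$carrier_ad, gt$carrier_nl,
                        gt$noncarrier_ad, gt$noncarrier_nl), 2,
                      byrow = TRUE)
        expect_equal(gt$chi2, chi2_oracle(tab), tolerance = 1e-10)
        expect_equal(gt$p_value, pchisq(chi2_oracle(tab), 1,
                                        lower.tail = FALSE),
                     tolerance = 1e-10)
    }

    ## p decreases as AD-only carrier count grows (equal group sizes)
    ps <- vapply(c(5, 10, 15, 20), function(k) {
        dos <- matrix(2L, 1, 100,
                      dimnames = list("X", sprintf("S%04d", 1:100)))
        dos[1, seq_len(k)] <- 1L
        groupFrequencyTest(make_dosage(dos),
                           make_pheno(100,
                                      cogdx = rep(c(4, 1),
                                                  each = 50)))$p_value
    }, numeric(1))
    expect_true(all(diff(ps) < 0))
})

test_that("carriers split by group sum to total carriers", {
    set.seed(31)
    coh <- generateCohort(simConfig(n_samples = 200, n_cnvs = 10,
                                    n_genes = 5,
                                    allele_freq_range = c(0.05, 0.2),
                                    seed = 31))
    fs <- summarizeFrequencies(coh$dosage)
    gt <- groupFrequencyTest(coh$dosage, coh$pheno)
    expect_equal(gt$carrier_ad + gt$carrier_nl, fs$carrier_count)
})

test_that("reciprocal-overlap validation applies the strict 50% rule", {
    q <- make_dosage(matrix(c(1L, 2L), 1, 2,
                            dimnames = list("DEL0001", c("a", "b"))))
    ## identical interval, same type
    db <- data.frame(chrom = "chr1", start = 1000, end = 1999,
                     type = "DEL", source_id = "E1")
    ov <- validateAgainstDb(q, db)
    expect_equal(c(ov$overlap_query, ov$overlap_db), c(1, 1))
    expect_true(ov$validated)

    ## boundary: exactly 0.5 reciprocal overlap fails (strictly greater)
    q2 <- CNVDosage(matrix(c(1L, 2L), 1, 2,
                           dimnames = list("DEL0001", c("a", "b"))),
                    "chr1", 1, 1000, "DEL")
    db2 <- data.frame(chrom = "chr1", start = 501, end = 1500,
                      type = "DEL", source_id = "E2")
    ov2 <- validateAgainstDb(q2, db2)
    expect_equal(c(ov2$overlap_query, ov2$overlap_db), c(0.5, 0.5))
    expect_false(ov2$validated)

    ## wrong type at identical span is never validated
    db3 <- data.frame(chrom = "chr1", start = 1, end = 1000,
                      type = "DUP", source_id = "E3")
    q3 <- CNVDosage(matrix(c(1L, 2L), 1, 2,
                           dimnames = list("DEL0001", c("a", "b"))),
                    "chr1", 1, 1000, "DEL")
    expect_false(validateAgainstDb(q3, db3)$validated)

    ## an mCNV query matches either type by default, but not when
    ## exact matching is requested
    q4 <- CNVDosage(matrix(c(1L, 3L), 1, 2,
                           dimnames = list("mCNV0001", c("a", "b"))),
                    "chr1", 1, 1000, "mCNV")
    expect_true(validateAgainstDb(q4, db3)$validated)
    expect_false(validateAgainstDb(q4, db3,
                                   mcnv_matches_any = FALSE)$validated)

    ## malformed database interval errors
    dbx <- data.frame(chrom = "chr1", start = 500, end = 100,
                      type = "DEL", source_id = "E4")
    expect_error(validateAgainstDb(q, dbx), "malformed")
})

test_that("reciprocal overlap is symmetric under interval swap", {
    set.seed(37)
    for (rep in 1:10) {
        s1 <- sample(1e4, 1); w1 <- sample(500:5000, 1)
        s2 <- s1 + sample(-2000:2000, 1); w2 <- sample(500:5000, 1)
        qa <- CNVDosage(matrix(c(1L, 2L), 1, 2,
                               dimnames = list("DEL0001", c("a", "b"))),
                        "chr1", s1, s1 + w1 - 1, "DEL")
        dba <- data.frame(chrom = "chr1", start = s2, end = s2 + w2 - 1,
                          type = "DEL", source_id = "E")
        qb <- CNVDosage(matrix(c(1L, 2L), 1, 2,
                               dimnames = list("DEL0001", c("a", "b"))),
                        "chr1", s2, s2 + w2 - 1, "DEL")
        dbb <- data.frame(chrom = "chr1", start = s1, end = s1 + w1 - 1,
                          type = "DEL", source_id = "E")
        oa <- validateAgainstDb(qa, dba)
        ob <- validateAgainstDb(qb, dbb)
        expect_equal(oa$overlap_query, ob$overlap_db)
        expect_equal(oa$overlap_db, ob$overlap_query)
    }
})
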