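test_that("linearAssoc matches the closed-form OLS solution", {
    ## exact fit
    r <- linearAssoc(3 * (1:10), 1:10)
    expect_equal(r$beta, 3, tolerance = 1e-12)
    expect_lt(r$p_value, 1e-12)

    ## normal-equations oracle, simple regression (p = 1)
    set.seed(59)
    for (rep in 1:5) {
        n <- 12
        x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
        sxx <- sum((x - mean(x))^2)
        beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sxx
        resid <- y - mean(y) - beta_hat * (x - mean(x))
        se_hat <- sqrt(sum(resid^2) / (n - 2) / sxx)
        t_hat <- beta_hat / se_hat
        r <- linearAssoc(y, x)
        expect_equal(r$beta, beta_hat, tolerance = 1e-10)
        expect_equal(r$se, se_hat, tolerance = 1e-10)
        expect_equal(r$t_stat, t_hat, tolerance = 1e-10)
        expect_equal(r$p_value, 2 * pt(abs(t_hat), n - 2,
                                       lower.tail = FALSE),
                     tolerance = 1e-10)
    }

    expect_error(linearAssoc(rnorm(10), rep(1, 10)), "constant")
    set.seed(60)
    x <- rnorm(20)
    expect_error(linearAssoc(rnorm(20), x, cbind(dup = x)),
                 "collinear.*dup")
})

test_that("covariate adjustment absorbs a covariate-driven response", {
    set.seed(61)
    n <- 2000
    sex <- rbinom(n, 1, 0.5)
    y <- 2 * sex + rnorm(n)
    x <- rnorm(n)
    r <- linearAssoc(y, x, cbind(sex = sex))
    expect_lt(abs(r$beta), 4 * r$se)
})

test_that("CNV-AOD scan excludes constant CNVs and recovers effects", {
    set.seed(67)
    n <- 1100
    pheno <- make_pheno(n, aod = NULL)
    dos <- matrix(2L, 3, n,
                  dimnames = list(c("FLAT", "DEL0001", "DEL0002"),
                                  rownames(pheno)))
    carriers <- sample(n, 22)
    dos["DEL0001", carriers] <- 1L
    dos["DEL0002", sample(n, 22)] <- 1L
    ## +10 years per copy deviation for DEL0001 carriers: dosage 1 is one
    ## copy below baseline, so beta on dosage is +10
    pheno$aod <- 80 + 10 * (dos["DEL0001", ] - 2) + rnorm(n, 0, 6)
    scan <- cnvAodScan(make_dosage(dos), pheno, trait = "cogdx")
    expect_false("FLAT" %in% scan$unit_a)
    hit <- scan[scan$unit_a == "DEL0001", ]
    expect_lt(abs(hit$beta - 10), 3 * hit$se)
    expect_true(hit$significant)
})

test_that("consensus across traits is a plain intersection", {
    sets <- list(cogdx = c("a", "b", "c"), braaksc = c("b", "c", "d"),
                 ceradsc = c("c", "b"))
    expect_setequal(consensusAcrossTraits(sets), c("b", "c"))
    sets$ceradsc <- character()
    expect_length(consensusAcrossTraits(sets), 0)
    same <- list(cogdx = c("x", "y"), braaksc = c("x", "y"),
                 ceradsc = c("x", "y"))
    expect_setequal(consensusAcrossTraits(same), c("x", "y"))
    expect_error(consensusAcrossTraits(same[1:2]), "missing trait")
})

test_that("eQTL scan recovers a planted dosage effect and m=1 BH", {
    set.seed(71)
    n <- 500
    pheno <- make_pheno(n)
    dos <- matrix(2L, 1, n, dimnames = list("DEL0001", rownames(pheno)))
    dos[1, sample(n, 25)] <- 1L
    expr <- rbind(target = 6 + 1.5 * (dos[1, ] - 2) + rnorm(n, 0, 0.5),
                  noise = rnorm(n, 6, 0.5))
    colnames(expr) <- rownames(pheno)
    scan <- cnvGeneScan(make_dosage(dos), expr, pheno, trait = "cogdx")
    hit <- scan[scan$unit_b == "target", ]
    expect_lt(abs(hit$beta - 1.5), 3 * hit$se)
    expect_true(hit$significant)

    ## single test: BH leaves the p-value unchanged
    one <- cnvGeneScan(make_dosage(dos), expr["target", , drop = FALSE],
                       pheno, trait = "cogdx")
    expect_equal(one$fdr, one$p_value)

    ## eQTL via lmFit agrees with linearAssoc on the same design
    ph <- pheno
    direct <- linearAssoc(expr["target", ], as.numeric(dos[1, ]),
                          cbind(sex = as.numeric(ph$sex),
                                trait = as.numeric(ph$cogdx)))
    expect_equal(hit$beta, direct$beta, tolerance = 1e-10)
    expect_equal(hit$p_value, direct$p_value, tolerance = 1e-10)
})

test_that("Spearman screen matches the rank-formula oracle", {
    pheno <- make_pheno(5, aod = c(70, 75, 80, 85, 88))
    ## strictly increasing in AOD -> rho exactly 1
    expr <- matrix(c(1, 2, 3, 4, 5), 1, 5,
                   dimnames = list("up", rownames(pheno)))
    r <- geneAodSpearman(expr, pheno)
    expect_equal(r$beta, 1)

    ## 5-point oracle via the sum-of-squared-rank-differences formula
    set.seed(73)
    for (rep in 1:10) {
        v <- sample(100, 5)  # no ties
        a <- sample(100, 5)
        ph <- make_pheno(5, aod = a)
        e <- matrix(v, 1, 5, dimnames = list("g", rownames(ph)))
        d2 <- sum((rank(v) - rank(a))^2)
        rho_oracle <- 1 - 6 * d2 / (5 * (25 - 1))
        expect_equal(geneAodSpearman(e, ph)$beta, rho_oracle,
                     tolerance = 1e-10)
    }

    ## invariance under strictly monotone transforms
    set.seed(74)
    ph <- make_pheno(30, aod = runif(30, 60, 90))
    v <- rnorm(30, 6)
    e1 <- matrix(v, 1, 30, dimnames = list("g", rownames(ph)))
    e2 <- matrix(exp(v), 1, 30, dimnames = list("g", rownames(ph)))
    expect_equal(geneAodSpearman(e1, ph)$beta,
                 geneAodSpearman(e2, ph)$beta, tolerance = 1e-12)

    ## tie handling agrees with the tie-corrected reference
    av <- c(70, 70, 80, 85, 85, 90, 64, 77)
    vv <- c(1, 2, 2, 3, 5, 5, 0, 2)
    ph <- make_pheno(8, aod = av)
    e <- matrix(vv, 1, 8, dimnames = list("g", rownames(ph)))
    ref <- suppressWarnings(cor.test(vv, av, method = "spearman"))
    expect_equal(geneAodSpearman(e, ph)$beta, unname(ref$estimate),
                 tolerance = 1e-12)

    ## constant gene skipped with a warning
    ph30 <- make_pheno(30, aod = runif(30, 60, 90))
    e3 <- rbind(g = v, flat = rep(1, 30))
    colnames(e3) <- rownames(ph30)
    expect_warning(r3 <- geneAodSpearman(e3, ph30), "constant")
    expect_equal(r3$unit_a, "g")
})

test_that("triplet assembly filters on all three screens", {
    cnv_aod <- data.frame(unit_a = c("c1", "c2"), unit_b = "AOD",
                          beta = c(10, -9), se = 1, t_stat = 1,
                          p_value = 0.001, fdr = c(0.01, 0.01),
                          trait_covariate = "cogdx",
                          significant = c(TRUE, TRUE))
    cnv_gene <- data.frame(unit_a = c("c1", "c1", "c2"),
                           unit_b = c("g1", "g2", "g3"),
                           beta = c(1.5, 1.2, -0.9), se = 0.1,
                           t_stat = 1, p_value = 0.001,
                           fdr = c(0.01, 0.01, 0.2),
                           trait_covariate = "cogdx",
                           significant = c(TRUE, TRUE, FALSE))
    gene_aod <- data.frame(unit_a = c("g1", "g2", "g3"), unit_b = "AOD",
                           beta = c(0.1, 0.12, 0.2), p_value = 0.001,
                           fdr = c(0.01, 0.3, 0.01),
                           significant = c(TRUE, FALSE, TRUE))
    tr <- assembleTriplets(cnv_aod, cnv_gene, gene_aod)
    ## g2 fails the gene screen, c2-g3 fails the pair screen
    expect_equal(nrow(tr), 1)
    expect_equal(tr$cnv_id, "c1")
    expect_equal(tr$gene_id, "g1")
    expect_equal(tr$beta_cnv_gene, 1.5)
    expect_equal(tr$beta_cnv_aod, 10)
    expect_equal(tr$rho_gene_aod, 0.1)

    ## row-order invariance
    tr2 <- assembleTriplets(cnv_aod[2:1, ], cnv_gene[3:1, ],
                            gene_aod[c(2, 3, 1), ])
    expect_identical(tr, tr2)

    ## empty CNV screen -> no triplets
    cnv_aod$significant <- FALSE
    expect_equal(nrow(assembleTriplets(cnv_aod, cnv_gene, gene_aod)), 0)
})
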