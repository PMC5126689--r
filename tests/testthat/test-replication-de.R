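test_that("TMM factors are unity for identical or purely rescaled columns", {
    set.seed(1)
    x <- rpois(200, 50) + 1L
    m <- cbind(a = x, b = x)
    expect_equal(unname(tmmFactors(m)), c(1, 1))
    ## pure library-size scaling: all M values 0, factors stay 1
    m2 <- cbind(a = x, b = 4L * x)
    expect_equal(unname(tmmFactors(m2)), c(1, 1))
})

test_that("TMM matches an independent transcription of the definition", {
    ## worked 6-gene example, computed by the oracle
    obs <- c(10L, 20L, 5L, 100L, 50L, 80L)
    ref <- c(12L, 18L, 40L, 90L, 55L, 30L)
    m <- cbind(ref = ref, obs = obs)
    f <- tmmFactors(m)
    raw <- oracleTmmPair(obs, ref)
    ## implementation rescales to geometric mean 1
    expect_equal(unname(f["obs"] / f["ref"]), raw, tolerance = 1e-10)
    ## larger random instance
    set.seed(21)
    mm <- matrix(rpois(5 * 300, 60) + 1L, ncol = 5,
                 dimnames = list(NULL, paste0("s", 1:5)))
    expect_equal(max(abs(tmmFactors(mm) -
                         edgeR::calcNormFactors(mm))), 0, tolerance = 1e-10)
})

test_that("TMM is invariant to a common integer rescaling of all columns", {
    set.seed(3)
    m <- matrix(rpois(4 * 250, 40) + 1L, ncol = 4)
    expect_equal(tmmFactors(m), tmmFactors(3L * m), tolerance = 1e-6)
    mz <- m; mz[, 2] <- 0L
    expect_error(tmmFactors(mz), "all-zero")
})

test_that("moment dispersion hits the Poisson limit and recovers NB overdispersion", {
    ann <- simulateAnnotation(50, 100, seed = 51)
    pois <- simulateCountCohort(ann, nPairs = 25, nControls = 0,
                                deFraction = 0, dispersion = 1e-8,
                                seed = 52)
    grp <- colData(pois$se)$tissue
    dPois <- nbDispersion(assay(pois$se), grp)
    expect_lt(dPois$common, 0.05)
    nb <- simulateCountCohort(ann, nPairs = 25, nControls = 0,
                              deFraction = 0, dispersion = 0.4, seed = 53)
    dNB <- nbDispersion(assay(nb$se), colData(nb$se)$tissue)
    expect_gt(dNB$common, 0.25)
    expect_lt(dNB$common, 0.6)
    ## constant columns within both groups: estimates floored at zero
    cm <- matrix(5L, 10, 4, dimnames = list(paste0("f", 1:10), NULL))
    d0 <- nbDispersion(cm, c("a", "a", "b", "b"), w = 0)
    expect_true(all(d0$perFeature == 0))
})

test_that("NB GLM test is null on identical groups and matches the Poisson GLM in the limit", {
    ann <- simulateAnnotation(20, 40, seed = 54)
    cc <- simulateCountCohort(ann, nPairs = 10, nControls = 0,
                              deFraction = 0, dispersion = 1e-6, seed = 55)
    counts <- assay(cc$se)
    ## same data labeled as both groups: LR statistic vanishes
    dup <- cbind(counts, counts)
    colnames(dup) <- paste0("s", seq_len(ncol(dup)))
    cd <- S4Vectors::DataFrame(
        sample_id = colnames(dup),
        tissue = rep(c("tumor", "adjacent"), each = ncol(counts)),
        row.names = colnames(dup))
    seDup <- SummarizedExperiment(assays = list(counts = dup), colData = cd)
    resDup <- nbTest(seDup, dispersion = rep(1e-8, nrow(dup)))
    expect_true(all(resDup$lr_stat < 1e-4, na.rm = TRUE))
    expect_true(all(resDup$p_raw > 0.99, na.rm = TRUE))
    ## phi -> 0, large counts: LRT p agrees with a Poisson GLM LRT
    res <- nbTest(cc$se, dispersion = rep(1e-8, nrow(counts)))
    grp <- factor(colData(cc$se)$tissue, levels = c("adjacent", "tumor"))
    offs <- log(colSums(counts) * tmmFactors(counts))
    pPois <- vapply(seq_len(nrow(counts)), function(i) {
        f1 <- glm(counts[i, ] ~ grp, family = poisson(), offset = offs)
        f0 <- glm(counts[i, ] ~ 1, family = poisson(), offset = offs)
        pchisq(f0$deviance - f1$deviance, 1, lower.tail = FALSE)
    }, numeric(1))
    ok <- res$p_raw > 1e-12 & pPois > 1e-12
    expect_true(all(abs(log(res$p_raw[ok]) - log(pPois[ok])) <
                    0.1 * abs(log(pPois[ok])) + 0.02))
})

test_that("NB GLM recovers a planted unit log2 fold change at 50 pairs", {
    ann <- simulateAnnotation(40, 60, seed = 56)
    cc <- simulateCountCohort(ann, nPairs = 50, nControls = 0,
                              deFraction = 0.3, log2fcMagnitude = 1,
                              probDown = 0.5, dispersion = 0.2, seed = 57)
    res <- nbTest(cc$se, covariates = c("age", "race", "batch"))
    planted <- match(cc$truth@deFeatures, res$feature_id)
    err <- abs(abs(res$log2fc[planted]) - 1)
    expect_lt(median(err), 0.15)
    ## reordering samples leaves the statistic unchanged
    se2 <- cc$se[, rev(seq_len(ncol(cc$se)))]
    res2 <- nbTest(se2, covariates = c("age", "race", "batch"))
    expect_equal(res2$lr_stat, res$lr_stat, tolerance = 1e-6)
})

test_that("replication rules reproduce the published two-stage table", {
    t2 <- replicationTable()
    expect_equal(nrow(t2), 37)
    disc <- data.frame(feature_id = t2$feature_id, log2fc = t2$disc_log2fc)
    paired <- data.frame(feature_id = t2$feature_id,
                         log2fc = t2$rep_paired_log2fc, p = t2$rep_paired_p)
    tvn <- data.frame(feature_id = t2$feature_id,
                      log2fc = t2$rep_tvn_log2fc, p = t2$rep_tvn_p)
    v <- replicationFilter(disc, paired, tvn)
    ## every printed row satisfies the paired criterion
    expect_equal(sum(v$passes_paired), 37)
    ## 30 of 37 also pass tumor-vs-healthy-normal (> 80%)
    expect_equal(sum(v$passes_tumor_vs_normal), 30)
    expect_gte(mean(v$passes_tumor_vs_normal), 0.80)
    ## the MEG3 row fails the tumor-vs-normal rule
    expect_false(v$passes_tumor_vs_normal[v$feature_id == "ENSG00000214548"])
    ## pure function: identical on re-run
    expect_identical(v, replicationFilter(disc, paired, tvn))
    ## missing feature excluded with a warning
    expect_warning(
        v2 <- replicationFilter(
            rbind(disc, data.frame(feature_id = "ENSG00000000000",
                                   log2fc = 2)), paired, tvn),
        "absent")
    expect_equal(nrow(v2), 37)
})

test_that("direction concordance compares the two stages' signs", {
    disc <- data.frame(feature_id = c("a", "b"), log2fc = c(2, -2))
    rep1 <- data.frame(feature_id = c("a", "b"), log2fc = c(1.5, 1.5),
                       p = c(0.01, 0.01))
    v <- replicationFilter(disc, rep1)
    expect_equal(v$direction_concordant, c(TRUE, FALSE))
    expect_true(all(is.na(v$passes_tumor_vs_normal)))
})
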