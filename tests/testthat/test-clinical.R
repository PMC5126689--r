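test_that("median split sends ties to the low group", {
    expect_equal(unname(medianSplit(c(1, 2, 3, 4))),
                 c("low", "low", "high", "high"))
    expect_equal(unname(medianSplit(c(1, 2, 3))), c("low", "low", "high"))
    expect_error(medianSplit(rep(2, 5)), "identical")
})

test_that("KM estimator matches hand product-limit computations", {
    ## no events: survival stays at 1
    km0 <- kmEstimate(c(2, 3, 5), c(0, 0, 0))
    expect_true(all(km0$survival == 1))
    ## {1 event, 2 censored, 3 event}: S(1) = 2/3, S(3) = 0
    km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
    expect_equal(km$survival[km$time == 1], 2 / 3)
    expect_equal(km$survival[km$time == 3], 0)
    ## duplicate event times: one combined drop
    km2 <- kmEstimate(c(1, 1, 2), c(1, 1, 0))
    expect_equal(km2$survival[km2$time == 1], 1 / 3)
    ## equals the hand oracle and, without censoring, the empirical survival
    set.seed(91)
    tt <- rexp(40); ev <- rbinom(40, 1, 0.7)
    km3 <- kmEstimate(tt, ev)
    orc <- oracleKM(tt, ev)
    expect_equal(km3$survival[km3$n_event > 0], orc$survival,
                 tolerance = 1e-12)
    ttc <- rexp(30)
    kmAll <- kmEstimate(ttc, rep(1, 30))
    expect_equal(kmAll$survival, vapply(kmAll$time,
                                        function(u) mean(ttc > u),
                                        numeric(1)), tolerance = 1e-12)
})

test_that("log-rank matches a textbook O-E computation and is null on identical groups", {
    time <- c(1, 2, 3, 4, 5, 6)
    event <- c(1, 1, 0, 1, 1, 1)
    group <- c("a", "b", "a", "b", "a", "b")
    lr <- logrankTest(time, event, group)
    orc <- oracleLogrank(time, event, group)
    expect_equal(lr$chi2, orc$chi2, tolerance = 1e-10)
    expect_equal(lr$p, orc$p, tolerance = 1e-10)
    ## same data in both groups
    t2 <- rep(c(1, 2, 3), 2); e2 <- rep(c(1, 0, 1), 2)
    g2 <- rep(c("a", "b"), each = 3)
    lr2 <- logrankTest(t2, e2, g2)
    expect_equal(lr2$chi2, 0, tolerance = 1e-12)
    expect_equal(lr2$p, 1)
})

test_that("hazard ratio is 1 on mirrored groups and flags monotone likelihoods", {
    t2 <- rep(c(1, 2, 3, 4), 2); e2 <- rep(c(1, 0, 1, 1), 2)
    g2 <- rep(c("low", "high"), each = 4)
    hz <- hazardRatio(t2, e2, g2)
    expect_equal(hz$hr, 1, tolerance = 1e-8)
    ## all events in one group before any in the other
    hzM <- hazardRatio(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0),
                       c("high", "high", "high", "low", "low", "low"))
    expect_true(hzM$monotone)
    ## agreement in direction with the log-rank O-E on a random fixture
    d <- simulateSurvival(120, hr = 2.5, censorRate = 0.1, seed = 92)
    hz2 <- hazardRatio(d$time, d$event, d$group)
    expect_gt(hz2$hr, 1)
    ## large-sample closed form: exponential rate ratio of the two arms
    d3 <- simulateSurvival(2000, hr = 2, censorRate = 0, seed = 93)
    mle <- (sum(d3$group == "high") / sum(d3$time[d3$group == "high"])) /
           (sum(d3$group == "low") / sum(d3$time[d3$group == "low"]))
    hz3 <- hazardRatio(d3$time, d3$event, d3$group)
    expect_equal(hz3$hr, mle, tolerance = 0.15)
})

test_that("HR estimation is consistent along a simulation ladder", {
    mae <- vapply(c(100, 400, 1600), function(n) {
        errs <- vapply(1:10, function(s) {
            d <- simulateSurvival(n, hr = 2, censorRate = 0, seed = n + s)
            abs(hazardRatio(d$time, d$event, d$group)$hr - 2)
        }, numeric(1))
        mean(errs)
    }, numeric(1))
    ## absolute error shrinks as the cohort grows
    expect_lt(mae[3], mae[1])
    expect_lt(mae[3], 0.15)
})

test_that("median-split survival screen finds an expression-linked hazard", {
    set.seed(94)
    n <- 200
    expr <- rbind(hit = rexp(n, 1), null = rexp(n, 1))
    grp <- ifelse(expr["hit", ] > median(expr["hit", ]), 2, 1)
    tt <- rexp(n, 0.05 * 3^(grp - 1))
    scr <- survivalScreen(expr, tt, rep(1L, n))
    expect_lt(scr$logrank_p[scr$feature_id == "hit"], 1e-4)
    expect_gt(scr$hr[scr$feature_id == "hit"], 1.5)
    expect_gt(scr$logrank_p[scr$feature_id == "null"], 0.001)
})

test_that("ER-specificity requires up-shift against both comparison classes", {
    set.seed(95)
    nPos <- 100; nNeg <- 50; nNorm <- 50
    base <- function(n) matrix(rexp(2 * n, 1), 2)
    mat <- cbind(base(nPos), base(nNeg), base(nNorm))
    rownames(mat) <- c("spec", "both")
    ## 'spec' is up in ER+ only; 'both' is up in all tumors
    mat["spec", 1:nPos] <- mat["spec", 1:nPos] * 4
    mat["both", 1:(nPos + nNeg)] <- mat["both", 1:(nPos + nNeg)] * 4
    colnames(mat) <- sprintf("s%03d", seq_len(ncol(mat)))
    cd <- S4Vectors::DataFrame(
        sample_id = colnames(mat),
        tissue = rep(c("tumor", "tumor", "normal"), c(nPos, nNeg, nNorm)),
        er_status = rep(c("ER+", "ER-", NA), c(nPos, nNeg, nNorm)),
        row.names = colnames(mat))
    se <- SummarizedExperiment(assays = list(fpkm = mat), colData = cd)
    res <- subtypeCompare(se)
    expect_true(res$er_specific[res$feature_id == "spec"])
    expect_false(res$er_specific[res$feature_id == "both"])
    ## identical class distributions: nothing flagged
    matNull <- matrix(rexp(2 * ncol(mat), 1), 2,
                      dimnames = dimnames(mat))
    seNull <- SummarizedExperiment(assays = list(fpkm = matNull),
                                   colData = cd)
    expect_false(any(subtypeCompare(seNull)$er_specific))
})
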