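mkFeat <- function(chrom, start, end, strand, id, biotype) {
    g <- GRanges(chrom, IRanges(start, end), strand = strand)
    mcols(g)$feature_id <- id
    mcols(g)$biotype <- biotype
    names(g) <- id
    g
}

test_that("nearest coding gene minimizes the boundary gap with a deterministic tie rule", {
    linc <- mkFeat("chr1", 10000, 12000, "+", "L", "lincRNA")
    genes <- c(mkFeat("chr1", 13221, 15000, "+", "G1", "protein_coding"),
               mkFeat("chr1", 17001, 19000, "+", "G2", "protein_coding"))
    nb <- nearestCodingGene(linc, genes)
    expect_equal(nb$gene, "G1")
    expect_equal(nb$distance, 1220)
    ## overlapping gene: distance 0
    ov <- mkFeat("chr1", 11000, 11500, "+", "G3", "protein_coding")
    expect_equal(nearestCodingGene(linc, c(genes, ov))$distance, 0)
    ## equidistant left/right: lower coordinate wins, flagged ambiguous
    eq <- c(mkFeat("chr1", 5000, 8999, "+", "GL", "protein_coding"),
            mkFeat("chr1", 13001, 15000, "+", "GR", "protein_coding"))
    nbEq <- nearestCodingGene(linc, eq)
    expect_equal(nbEq$gene, "GL")
    expect_true(nbEq$ambiguous)
    ## no coding gene on the chromosome: omitted with a warning
    far <- mkFeat("chr9", 1, 100, "+", "GX", "protein_coding")
    expect_warning(none <- nearestCodingGene(linc, far), "omitted")
    expect_null(none)
})

test_that("orientation truth table: divergent, same-strand and convergent geometries", {
    l <- function(s) mkFeat("chr1", 1000, 2000, s, "L", "lincRNA")
    g <- function(s) mkFeat("chr1", 3000, 4000, s, "G", "protein_coding")
    ## linc on -, gene on + to its right: 5' ends face across the gap
    expect_equal(classifyOrientation(l("-"), g("+")), "H2H")
    expect_equal(classifyOrientation(l("+"), g("+")), "H2T")
    expect_equal(classifyOrientation(l("-"), g("-")), "H2T")
    ## linc on + left of gene on -: 3' ends face
    expect_equal(classifyOrientation(l("+"), g("-")), "T2T")
    ## symmetric under swapping the two features
    expect_equal(classifyOrientation(g("+"), l("-")), "H2H")
    expect_equal(classifyOrientation(g("-"), l("+")), "T2T")
    ## flipping both strands maps H2H <-> T2T and fixes H2T
    expect_equal(classifyOrientation(l("+"), g("-")), "T2T")
    expect_equal(classifyOrientation(l("-"), g("+")), "H2H")
})

test_that("fold-change concordance is an OLS fit with its degenerate cases", {
    pairs <- data.frame(linc = paste0("L", 1:10), gene = paste0("G", 1:10))
    x <- setNames(rnorm(10), pairs$gene)
    ## a perfect fit makes the slope test degenerate; only r2/slope matter
    exact <- suppressWarnings(
        fcConcordance(pairs, setNames(x[pairs$gene], pairs$linc), x))
    expect_equal(exact$r2, 1)
    expect_equal(exact$slope, 1)
    flat <- fcConcordance(pairs, setNames(rnorm(10), pairs$linc),
                          setNames(rep(2, 10), pairs$gene))
    expect_true(is.na(flat$r2))
    ## independent fold changes rarely produce structure at n = 85
    set.seed(5)
    bigPairs <- data.frame(linc = paste0("L", 1:85), gene = paste0("G", 1:85))
    r2s <- vapply(1:20, function(i) {
        fcConcordance(bigPairs,
                      setNames(rnorm(85), bigPairs$linc),
                      setNames(rnorm(85), bigPairs$gene))$r2
    }, numeric(1))
    expect_gte(mean(r2s < 0.1), 0.95)
})

test_that("planted divergent pairs beat random pairs in both rho and FC concordance", {
    ann <- simulateAnnotation(40, 80,
                              orientationMix = c(H2H = 1, H2T = 0, T2T = 0),
                              seed = 71)
    fp <- simulateFpkmCohort(ann, nPairs = 85, deFraction = 0.5,
                             log2fcMagnitude = 2, neighborRho = 0.5,
                             sparsity = 0, seed = 72)
    adj <- colnames(fp$se)[colData(fp$se)$tissue == "adjacent"]
    nb <- pairwiseSpearman(fp$se, ann$pairs, adj)
    lincs <- ann$catalog[ann$catalog$biotype == "lincRNA"]
    genes <- ann$catalog[ann$catalog$biotype == "protein_coding"]
    rnd <- pairNulls(lincs, genes, "random", nRandom = 500, seed = 73)
    rnd <- pairwiseSpearman(fp$se, rnd, adj)
    ## distribution shift: planted-neighbor median beats the random 95th pct
    expect_gt(median(nb$rho), quantile(rnd$rho, 0.95, na.rm = TRUE))
    ## FC concordance: planted pairs structured, random pairs not
    de <- discoveryDE(fp$se)
    lfc <- setNames(de$log2fc, de$feature_id)
    fcN <- fcConcordance(ann$pairs, lfc, lfc)
    fcR <- fcConcordance(rnd, lfc, lfc)
    expect_gt(fcN$r2, fcR$r2)
    expect_lt(fcN$p, 0.001)
})

test_that("null pair construction respects the distance rule and seeding", {
    ann <- simulateAnnotation(10, 30, seed = 74)
    lincs <- ann$catalog[ann$catalog$biotype == "lincRNA"]
    genes <- ann$catalog[ann$catalog$biotype == "protein_coding"]
    nn <- pairNulls(lincs, genes, "non_neighbor", seed = 75)
    ## every chosen gene is > 1 Mb away or on another chromosome
    for (i in seq_len(nrow(nn))) {
        l <- lincs[nn$linc[i]]; g <- genes[nn$gene[i]]
        if (as.character(seqnames(l)) == as.character(seqnames(g))) {
            expect_gt(GenomicRanges::distance(l, g, ignore.strand = TRUE),
                      1e6)
        } else succeed()
    }
    expect_identical(nn, pairNulls(lincs, genes, "non_neighbor", seed = 75))
    rnd <- pairNulls(lincs, genes, "random", nRandom = 1000, seed = 76)
    expect_equal(nrow(rnd), 1000)
    ## all genes within 1 Mb: empty result with warnings
    near <- mkFeat("chr1", start(lincs[1]) + 5000, start(lincs[1]) + 6000,
                   "+", "GN", "protein_coding")
    expect_warning(empty <- pairNulls(lincs[1], near, "non_neighbor",
                                      seed = 1), "skipped")
    expect_null(empty)
})

test_that("one-sided binomial enrichment for divergent pairs", {
    expect_equal(h2hEnrichment(0, 37, 0.3), 1)
    expect_equal(h2hEnrichment(3, 3, 0.5), 0.125)
    ## at the published counts (14 of 37) a plausible baseline gives the
    ## marginal regime
    p <- h2hEnrichment(14, 37, 0.27)
    expect_gt(p, 0.01)
    expect_lt(p, 0.2)
})

test_that("pairwise Spearman equals a rank-then-Pearson oracle", {
    x <- c(3.1, 0.2, 5.5, 2.2, 4.4)
    y <- c(0.1, 0.9, 0.4, 0.8, 0.2)
    mat <- rbind(L = x, G = y)
    se <- SummarizedExperiment(
        assays = list(fpkm = mat),
        colData = S4Vectors::DataFrame(row.names = paste0("s", 1:5)))
    pr <- pairwiseSpearman(se, data.frame(linc = "L", gene = "G"))
    expect_equal(pr$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    ## perfect concordance / reversal
    se2 <- SummarizedExperiment(assays = list(fpkm = rbind(L = 1:5,
                                                           G = c(2, 4, 6, 8, 10),
                                                           H = 5:1)),
        colData = S4Vectors::DataFrame(row.names = paste0("s", 1:5)))
    both <- pairwiseSpearman(se2, data.frame(linc = c("L", "L"),
                                             gene = c("G", "H")))
    expect_equal(both$rho, c(1, -1))
    ## constant member: flagged, rho NA
    se3 <- SummarizedExperiment(assays = list(fpkm = rbind(L = 1:5,
                                                           G = rep(2, 5))),
        colData = S4Vectors::DataFrame(row.names = paste0("s", 1:5)))
    d <- pairwiseSpearman(se3, data.frame(linc = "L", gene = "G"))
    expect_true(d$degenerate)
    expect_true(is.na(d$rho))
})
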