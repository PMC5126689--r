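## Shared fixture builders and independent oracles. Oracles are deliberately
## written as direct transcriptions of the definitions (enumeration, brute
## force) and share no code with the implementation paths they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

## Minimal paired SummarizedExperiment from tumor/normal matrices.
makePairedSE <- function(tumor, normal, unit = "FPKM") {
    stopifnot(identical(dim(tumor), dim(normal)))
    n <- ncol(tumor)
    mat <- matrix(0, nrow(tumor), 2 * n)
    mat[, seq(1, 2 * n, 2)] <- tumor
    mat[, seq(2, 2 * n, 2)] <- normal
    pid <- sprintf("P%02d", rep(seq_len(n), each = 2))
    sid <- paste0(pid, c("_T", "_A"))
    rownames(mat) <- if (is.null(rownames(tumor)))
        sprintf("F%03d", seq_len(nrow(tumor))) else rownames(tumor)
    colnames(mat) <- sid
    se <- SummarizedExperiment(
        assays = setNames(list(mat), tolower(unit)),
        colData = S4Vectors::DataFrame(
            sample_id = sid,
            tissue = rep(c("tumor", "adjacent"), n),
            pair_id = pid, row.names = sid))
    S4Vectors::metadata(se)$unit <- unit
    se
}

## Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
enumSignedRankP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    sObs <- sum(sign(d) * r)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    sAll <- as.vector(signs %*% r)
    mean(abs(sAll) >= abs(sObs) - 1e-9)
}

## Direct transcription of the TMM definition for a sample against a
## reference column: double trim on M (each tail trimM) and A (each tail
## trimA), inverse-variance weighted mean of kept M values.
oracleTmmPair <- function(obs, ref, trimM = 0.30, trimA = 0.05) {
    nO <- sum(obs); nR <- sum(ref)
    keep <- obs > 0 & ref > 0
    o <- obs[keep]; r <- ref[keep]
    M <- log2((o / nO) / (r / nR))
    A <- 0.5 * log2((o / nO) * (r / nR))
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    n <- length(M)
    ## midrank trimming so tied log-ratios are kept or dropped together
    keepM <- rank(M) >= floor(n * trimM) + 1 & rank(M) <= n - floor(n * trimM)
    keepA <- rank(A) >= floor(n * trimA) + 1 & rank(A) <= n - floor(n * trimA)
    sel <- keepM & keepA
    2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
}

## Brute-force nearest coding gene: per lincRNA scan every gene.
oracleNearest <- function(lincs, genes) {
    res <- lapply(seq_along(lincs), function(i) {
        l <- lincs[i]
        dd <- vapply(seq_along(genes), function(j) {
            g <- genes[j]
            if (as.character(seqnames(g)) != as.character(seqnames(l)))
                return(Inf)
            if (start(g) > end(l)) start(g) - end(l) - 1
            else if (start(l) > end(g)) start(l) - end(g) - 1
            else 0
        }, numeric(1))
        best <- which(dd == min(dd))
        if (length(best) > 1) best <- best[which.min(start(genes)[best])]
        data.frame(linc = l$feature_id, gene = genes$feature_id[best],
                   distance = min(dd))
    })
    do.call(rbind, res)
}

## Brute-force TF edge assignment: all peak x lincRNA window pairs.
oracleEdges <- function(lincs, peaks, upstream = 2000) {
    out <- list()
    for (i in seq_along(peaks)) {
        p <- peaks[i]
        for (j in seq_along(lincs)) {
            l <- lincs[j]
            if (as.character(seqnames(p)) != as.character(seqnames(l)))
                next
            if (as.character(strand(l)) == "+") {
                ws <- max(1, start(l) - upstream); we <- end(l)
            } else {
                ws <- start(l); we <- end(l) + upstream
            }
            if (start(p) <= we && end(p) >= ws)
                out[[length(out) + 1]] <- data.frame(
                    tf = p$tf, linc = l$feature_id)
        }
    }
    unique(do.call(rbind, out))
}

## Hand product-limit estimator (no package code): returns survival at each
## distinct event time.
oracleKM <- function(time, event) {
    ts <- sort(unique(time[event == 1]))
    s <- 1
    out <- numeric(length(ts))
    for (k in seq_along(ts)) {
        atRisk <- sum(time >= ts[k])
        d <- sum(time == ts[k] & event == 1)
        s <- s * (1 - d / atRisk)
        out[k] <- s
    }
    data.frame(time = ts, survival = out)
}

## Textbook log-rank O-E chi-square for two groups.
oracleLogrank <- function(time, event, group) {
    g <- unique(group)
    ts <- sort(unique(time[event == 1]))
    O <- E <- V <- 0
    for (tk in ts) {
        n1 <- sum(time >= tk & group == g[1])
        n2 <- sum(time >= tk & group == g[2])
        d1 <- sum(time == tk & event == 1 & group == g[1])
        d2 <- sum(time == tk & event == 1 & group == g[2])
        n <- n1 + n2; d <- d1 + d2
        if (n < 2) next
        O <- O + d1
        E <- E + d * n1 / n
        V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
    }
    chi2 <- (O - E)^2 / V
    list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}
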