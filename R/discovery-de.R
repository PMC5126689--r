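## Discovery-stage paired differential expression: per-feature log2 fold
## change, Wilcoxon signed-rank testing on tumor-minus-adjacent differences,
## BH adjustment, the within-pair sign-flip permutation FDR estimator, and
## the discovery selection rule (FC >= 2, BH P < 0.01, permutation FDR < 1%).

#' Log2 fold change of group means
#'
#' \code{log2((mean(tumor) + eps) / (mean(normal) + eps))}. With both groups
#' all-zero the fold change is 0 and flagged.
#'
#' @param tumor,normal numeric vectors of equal length.
#' @param eps pseudocount guarding against zero means.
#' @return numeric scalar; \code{attr(, "allZero")} is TRUE when both group
#'   means are zero.
#' @export
log2FoldChange <- function(tumor, normal, eps = 0.1) {
    stopifnot(length(tumor) == length(normal), length(tumor) >= 1)
    mt <- mean(tumor); mn <- mean(normal)
    if (mt == 0 && mn == 0) {
        out <- 0
        attr(out, "allZero") <- TRUE
        return(out)
    }
    log2((mt + eps) / (mn + eps))
}

## Signed midranks of paired differences, zeros dropped (rank 0).
## Returns list(R = signed-rank matrix, v = rowSums(R^2)).
signedRankMatrix <- function(D) {
    R <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
    for (i in seq_len(nrow(D))) {
        d <- D[i, ]
        nz <- which(d != 0)
        if (length(nz))
            R[i, nz] <- sign(d[nz]) * rank(abs(d[nz]))
    }
    list(R = R, v = rowSums(R^2))
}

## p-value for one signed-rank statistic: exact via the null distribution of
## W+ when n <= 25 with untied nonzero |d|, else normal approximation with
## continuity correction on W+.
signedRankP <- function(r) {
    r <- r[r != 0]
    n <- length(r)
    if (n == 0) return(1)
    wPlus <- sum(r[r > 0])
    ties <- anyDuplicated(abs(r)) > 0
    if (n <= 25 && !ties) {
        p <- 2 * min(stats::psignrank(wPlus, n),
                     stats::psignrank(wPlus - 1, n, lower.tail = FALSE))
        return(min(1, p))
    }
    ex <- n * (n + 1) / 4
    sigma <- sqrt(sum(r^2)) / 2      # sd of W+ with midrank tie correction
    z <- (wPlus - ex - sign(wPlus - ex) * 0.5) / sigma
    min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon signed-rank test on paired samples
#'
#' Zero differences are dropped before ranking; ties get midranks. The
#' statistic is the signed standardized rank sum
#' \eqn{Z = \sum sign(d_i) r_i / \sqrt{\sum r_i^2}}. The p-value is exact
#' (all sign assignments) for n <= 25 without ties, otherwise a normal
#' approximation with continuity correction.
#'
#' @param tumor,normal paired numeric vectors.
#' @return list: \code{statistic} (signed Z), \code{p}.
#' @export
pairedWilcoxon <- function(tumor, normal) {
    stopifnot(length(tumor) == length(normal))
    d <- tumor - normal
    nz <- d[d != 0]
    if (length(nz) == 0) return(list(statistic = 0, p = 1))
    if (length(nz) < 3)
        stop("need at least 3 non-zero paired differences")
    r <- sign(nz) * rank(abs(nz))
    list(statistic = sum(r) / sqrt(sum(r^2)), p = signedRankP(r))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}, kept as a named
#' step so the pipeline's multiplicity handling is explicit.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

## Extract paired tumor/adjacent matrices (columns aligned by pair_id).
pairedMatrices <- function(se) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    mat <- SummarizedExperiment::assay(se, 1L)
    keep <- cd$tissue %in% c("tumor", "adjacent") & !is.na(cd$pair_id)
    cd <- cd[keep, , drop = FALSE]
    mat <- mat[, keep, drop = FALSE]
    pairs <- intersect(cd$pair_id[cd$tissue == "tumor"],
                       cd$pair_id[cd$tissue == "adjacent"])
    if (length(pairs) < 3) stop("need at least 3 complete tumor/adjacent pairs")
    ti <- match(pairs, ifelse(cd$tissue == "tumor", cd$pair_id, NA))
    ai <- match(pairs, ifelse(cd$tissue == "adjacent", cd$pair_id, NA))
    list(tumor = mat[, ti, drop = FALSE], normal = mat[, ai, drop = FALSE],
         pairs = pairs)
}

#' Discovery-stage differential expression table
#'
#' Per feature: mean-based log2 fold change (tumor vs adjacent), signed
#' standardized Wilcoxon signed-rank statistic, raw and BH-adjusted p.
#'
#' @param se paired FPKM \code{SummarizedExperiment} (colData needs
#'   \code{tissue} and \code{pair_id}).
#' @param eps pseudocount for the fold change.
#' @return data.frame: \code{feature_id}, \code{log2fc}, \code{statistic},
#'   \code{p_raw}, \code{p_bh}.
#' @export
discoveryDE <- function(se, eps = 0.1) {
    pm <- pairedMatrices(se)
    D <- pm$tumor - pm$normal
    sr <- signedRankMatrix(D)
    z <- ifelse(sr$v > 0, rowSums(sr$R) / sqrt(pmax(sr$v, 1e-300)), 0)
    p <- apply(sr$R, 1L, signedRankP)
    lfc <- log2((rowMeans(pm$tumor) + eps) / (rowMeans(pm$normal) + eps))
    data.frame(feature_id = rownames(D), log2fc = lfc, statistic = z,
               p_raw = p, p_bh = bhAdjust(p),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation-based FDR estimation for paired DE
#'
#' The null is generated by independently swapping the tumor/adjacent labels
#' within each pair (a sign flip of the paired difference), which leaves the
#' ranks of |difference| untouched -- so all \code{B} permutation statistics
#' are obtained exactly from the observed signed-rank matrix times a random
#' sign matrix. For each threshold \code{d} the FDR is estimated as the mean
#' permuted count of |statistic| >= d divided by the observed count, capped
#' at 1 and monotonized by cumulative minimum from large \code{d} downward.
#'
#' @param se paired FPKM \code{SummarizedExperiment}.
#' @param B number of permutations.
#' @param dGrid thresholds on |statistic|; default the sorted distinct
#'   observed |statistic| values.
#' @param seed integer seed for the sign flips.
#' @param identityPermutation test hook: force every permutation to be the
#'   identity (no flips), so the estimate is 1 at every achieved threshold.
#' @return \code{PermutationFDR}
#' @export
permutationFdr <- function(se, B = 1000, dGrid = NULL, seed = 1L,
                           identityPermutation = FALSE) {
    stopifnot(B >= 1)
    pm <- pairedMatrices(se)
    D <- pm$tumor - pm$normal
    sr <- signedRankMatrix(D)
    sd0 <- sqrt(pmax(sr$v, 1e-300))
    zObs <- rowSums(sr$R) / sd0
    nPairs <- ncol(D)
    E <- withSeed(seed, {
        if (identityPermutation) matrix(1, nPairs, B)
        else matrix(sample(c(-1, 1), nPairs * B, replace = TRUE), nPairs, B)
    })
    zPerm <- (sr$R %*% E) / sd0
    if (is.null(dGrid)) dGrid <- sort(unique(abs(zObs)))
    dGrid <- sort(dGrid)
    absObs <- sort(abs(zObs))
    absPerm <- sort(abs(as.vector(zPerm)))
    nGE <- function(sortedX, d)    # #{x >= d}
        length(sortedX) - findInterval(d - 1e-12, sortedX)
    rObs <- vapply(dGrid, function(d) nGE(absObs, d), numeric(1))
    rPerm <- vapply(dGrid, function(d) nGE(absPerm, d), numeric(1)) / B
    fdr <- ifelse(rObs > 0, pmin(1, rPerm / rObs), NA_real_)
    ## enforce non-increasing in d: running minimum over ascending d
    ok <- !is.na(fdr)
    fdr[ok] <- cummin(fdr[ok])
    new("PermutationFDR", d = as.numeric(dGrid), rObs = as.integer(rObs),
        rPermMean = rPerm, fdr = fdr, B = as.integer(B),
        seed = as.integer(seed))
}

#' Smallest statistic threshold achieving a target estimated FDR
#'
#' @param permfdr a \code{PermutationFDR}.
#' @param fdrMax target estimated FDR.
#' @return numeric threshold on |statistic|, or \code{Inf} (with a warning)
#'   when no grid point achieves the target.
#' @export
permutationThreshold <- function(permfdr, fdrMax = 0.01) {
    ok <- which(!is.na(permfdr@fdr) & permfdr@fdr < fdrMax)
    if (!length(ok)) {
        warning("no threshold achieves estimated FDR < ", fdrMax)
        return(Inf)
    }
    permfdr@d[min(ok)]
}

#' Discovery-stage DE selection
#'
#' A feature is selected iff its absolute fold change is at least
#' \code{fcMin} (i.e. |log2FC| >= log2(fcMin)), its BH-adjusted p is below
#' \code{bhMax}, and its |statistic| is at or above the smallest threshold
#' with permutation-estimated FDR below \code{fdrMax}.
#'
#' @param de data.frame from \code{discoveryDE}.
#' @param permfdr \code{PermutationFDR} computed on the same matrix.
#' @param fcMin minimum fold change (linear scale).
#' @param bhMax maximum BH-adjusted p.
#' @param fdrMax maximum permutation-estimated FDR.
#' @return character vector of selected feature ids (empty, with a warning
#'   from \code{permutationThreshold}, when no threshold achieves the FDR).
#' @export
selectDE <- function(de, permfdr, fcMin = 2, bhMax = 0.01, fdrMax = 0.01) {
    dStar <- permutationThreshold(permfdr, fdrMax)
    sel <- abs(de$log2fc) >= log2(fcMin) & de$p_bh < bhMax &
        abs(de$statistic) >= dStar
    de$feature_id[sel]
}
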