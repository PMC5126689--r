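## Neighboring-gene analysis: nearest protein-coding partner per lincRNA,
## transcriptional orientation (H2H divergent / H2T same-strand / T2T
## convergent), fold-change concordance, non-neighbor and random-pair nulls,
## the one-sided binomial H2H enrichment, and pairwise Spearman correlation.

#' Nearest protein-coding gene per lincRNA
#'
#' Distance is the gap between the closest feature boundaries, strand
#' ignored, and 0 when the features overlap or are adjacent. Equidistant
#' ties are broken toward the lower-coordinate gene and flagged.
#'
#' @param lincs \code{GRanges} with mcol \code{feature_id}.
#' @param genes \code{GRanges} protein-coding catalog with mcol
#'   \code{feature_id}.
#' @return data.frame: \code{linc}, \code{gene}, \code{distance},
#'   \code{orientation}, \code{ambiguous}. lincRNAs on chromosomes with no
#'   coding gene are omitted with a warning.
#' @export
nearestCodingGene <- function(lincs, genes) {
    stopifnot(length(genes) >= 1)
    out <- vector("list", length(lincs))
    skipped <- 0L
    for (i in seq_along(lincs)) {
        l <- lincs[i]
        cand <- genes[as.character(seqnames(genes)) ==
                      as.character(seqnames(l))]
        if (!length(cand)) { skipped <- skipped + 1L; next }
        d <- distance(rep(l, length(cand)), cand, ignore.strand = TRUE)
        best <- which(d == min(d))
        amb <- length(best) > 1
        if (amb) best <- best[which.min(start(cand)[best])]
        g <- cand[best[1]]
        out[[i]] <- data.frame(
            linc = mcols(l)$feature_id,
            gene = mcols(g)$feature_id,
            distance = min(d),
            orientation = classifyOrientation(l, g),
            ambiguous = amb,
            stringsAsFactors = FALSE)
    }
    if (skipped)
        warning(skipped, " lincRNA(s) with no coding gene on their chromosome omitted")
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Transcriptional orientation of a feature pair
#'
#' Same strand is head-to-tail (H2T). On opposite strands the pair is
#' head-to-head (H2H, divergent) when the two 5' ends face each other across
#' the gap -- i.e. the leftmost feature is on the minus strand -- and
#' tail-to-tail (T2T, convergent) when the 3' ends face. Overlapping
#' opposite-strand pairs are classified by the same 5'-end geometry (using
#' start coordinates to decide left/right).
#'
#' @param a,b single-range \code{GRanges} on one chromosome.
#' @return \code{"H2H"}, \code{"H2T"} or \code{"T2T"}.
#' @export
classifyOrientation <- function(a, b) {
    sa <- as.character(strand(a)); sb <- as.character(strand(b))
    if (sa == sb) return("H2T")
    left <- if (start(a) <= start(b)) sa else sb
    if (left == "-") "H2H" else "T2T"
}

#' Fold-change concordance of lincRNA/gene pairs
#'
#' Ordinary least squares of the lincRNA log2 fold change on the partner
#' gene log2 fold change; reports the slope, r-squared and the slope-test p.
#'
#' @param pairs data.frame with columns \code{linc}, \code{gene}.
#' @param lincLog2fc,geneLog2fc named numeric vectors of log2 fold changes.
#' @return list: \code{slope}, \code{r2}, \code{p}, \code{n}.
#' @export
fcConcordance <- function(pairs, lincLog2fc, geneLog2fc) {
    x <- geneLog2fc[pairs$gene]
    y <- lincLog2fc[pairs$linc]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) stop("need at least 3 pairs with finite fold changes")
    if (stats::sd(x[ok]) == 0)
        return(list(slope = NA_real_, r2 = NA_real_, p = NA_real_,
                    n = sum(ok)))
    fit <- stats::lm(y[ok] ~ x[ok])
    s <- summary(fit)
    list(slope = unname(stats::coef(fit)[2]),
         r2 = s$r.squared,
         p = s$coefficients[2, 4],
         n = sum(ok))
}

#' Null pair sets: non-neighboring and random lincRNA/gene pairs
#'
#' \code{non_neighbor}: for each lincRNA, one uniformly chosen coding gene
#' more than \code{minGap} bp away (or on another chromosome).
#' \code{random}: \code{nRandom} uniform (lincRNA, gene) pairs regardless of
#' distance.
#'
#' @param lincs,genes \code{GRanges} catalogs with mcol \code{feature_id}.
#' @param mode \code{"non_neighbor"} or \code{"random"}.
#' @param minGap minimum gap for non-neighbors, bp.
#' @param nRandom number of random pairs.
#' @param seed integer seed.
#' @return data.frame: \code{linc}, \code{gene}.
#' @export
pairNulls <- function(lincs, genes, mode = c("non_neighbor", "random"),
                      minGap = 1e6, nRandom = 1000, seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(length(lincs) >= 1, length(genes) >= 1)
    withSeed(seed, {
        if (mode == "random") {
            data.frame(
                linc = mcols(lincs)$feature_id[
                    sample.int(length(lincs), nRandom, replace = TRUE)],
                gene = mcols(genes)$feature_id[
                    sample.int(length(genes), nRandom, replace = TRUE)],
                stringsAsFactors = FALSE)
        } else {
            out <- vector("list", length(lincs))
            skipped <- 0L
            for (i in seq_along(lincs)) {
                l <- lincs[i]
                sameChrom <- as.character(seqnames(genes)) ==
                    as.character(seqnames(l))
                d <- rep(Inf, length(genes))
                if (any(sameChrom))
                    d[sameChrom] <- distance(rep(l, sum(sameChrom)),
                                             genes[sameChrom],
                                             ignore.strand = TRUE)
                eligible <- which(d > minGap)
                if (!length(eligible)) { skipped <- skipped + 1L; next }
                out[[i]] <- data.frame(
                    linc = mcols(l)$feature_id,
                    gene = mcols(genes)$feature_id[
                        eligible[sample.int(length(eligible), 1)]],
                    stringsAsFactors = FALSE)
            }
            if (skipped)
                warning(skipped, " lincRNA(s) with no eligible non-neighbor gene skipped")
            do.call(rbind, out[!vapply(out, is.null, logical(1))])
        }
    })
}

#' One-sided binomial test for head-to-head over-representation
#'
#' Upper-tail probability P[X >= k] with X ~ Binomial(n, p0), where p0 is
#' the genome-wide proportion of H2H orientation among lincRNA/nearest-gene
#' pairs.
#'
#' @param kH2H observed H2H pairs among the DE set.
#' @param nPairs total DE pairs.
#' @param p0 baseline H2H proportion in (0, 1).
#' @return one-sided p-value.
#' @export
h2hEnrichment <- function(kH2H, nPairs, p0) {
    stopifnot(kH2H >= 0, kH2H <= nPairs, p0 > 0, p0 < 1)
    stats::pbinom(kH2H - 1, nPairs, p0, lower.tail = FALSE)
}

#' Spearman correlation per lincRNA/gene pair
#'
#' Rank correlation with midranks for ties, computed over a chosen sample
#' subset (e.g. the adjacent-normal tissues). Pairs where either member is
#' constant get NA with a flag.
#'
#' @param se expression \code{SummarizedExperiment}.
#' @param pairs data.frame with columns \code{linc}, \code{gene}.
#' @param samples optional character vector of sample ids (default all).
#' @return the \code{pairs} data.frame with added columns \code{rho} and
#'   \code{degenerate}.
#' @export
pairwiseSpearman <- function(se, pairs, samples = NULL) {
    mat <- SummarizedExperiment::assay(se, 1L)
    if (!is.null(samples)) mat <- mat[, samples, drop = FALSE]
    if (ncol(mat) < 4) stop("need at least 4 samples for rank correlation")
    rho <- rep(NA_real_, nrow(pairs))
    degenerate <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        x <- mat[pairs$linc[i], ]
        y <- mat[pairs$gene[i], ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
            degenerate[i] <- TRUE
            next
        }
        rho[i] <- stats::cor(x, y, method = "spearman")
    }
    pairs$rho <- rho
    pairs$degenerate <- degenerate
    pairs
}
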