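## Function inference by co-expression: a shuffled-pair null for the
## Spearman coefficient, the symmetric |rho| >= 0.4 co-expression call, and
## hypergeometric gene-set enrichment with BH adjustment over user-supplied
## sets (a standard open replacement for web-service annotation tools).

#' Shuffled-pair null distribution of the Spearman coefficient
#'
#' Draws \code{nShuffles} uniform (lincRNA, coding gene) pairings and
#' computes the Spearman correlation for each, yielding the null
#' distribution against which the co-expression cutoff is judged. When the
#' number of possible pairs is below \code{nShuffles} the draws are with
#' replacement (they are anyway); noted for completeness.
#'
#' @param lincMat numeric matrix, lincRNAs x samples.
#' @param codingMat numeric matrix, coding genes x samples (same samples).
#' @param nShuffles number of random pairings.
#' @param seed integer seed.
#' @return list: \code{rho} (length \code{nShuffles}), \code{quantiles}
#'   (the 0.5% and 99.5% empirical quantiles).
#' @export
shuffledNullRho <- function(lincMat, codingMat, nShuffles = 1000, seed = 1L) {
    stopifnot(ncol(lincMat) == ncol(codingMat), ncol(lincMat) >= 4)
    withSeed(seed, {
        iL <- sample.int(nrow(lincMat), nShuffles, replace = TRUE)
        iG <- sample.int(nrow(codingMat), nShuffles, replace = TRUE)
        rho <- vapply(seq_len(nShuffles), function(k) {
            x <- lincMat[iL[k], ]; y <- codingMat[iG[k], ]
            if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
            stats::cor(x, y, method = "spearman")
        }, numeric(1))
        list(rho = rho,
             quantiles = stats::quantile(rho, c(0.005, 0.995), na.rm = TRUE))
    })
}

#' Co-expressed gene set of one lincRNA
#'
#' Genes whose Spearman correlation with the lincRNA satisfies
#' |rho| >= \code{threshold} (both signs kept, annotated). The default 0.4
#' is chosen to sit above the shuffled-pair null.
#'
#' @param lincValues numeric vector, the lincRNA's expression across
#'   samples.
#' @param codingMat numeric matrix, coding genes x the same samples.
#' @param threshold symmetric cutoff on |rho| (>= 0).
#' @return list: \code{rho} (named vector over genes), \code{coexpressed}
#'   (data.frame \code{gene}, \code{rho}, \code{sign}), \code{degenerate}
#'   (TRUE when the lincRNA is constant, with an empty set).
#' @export
coexpressedSet <- function(lincValues, codingMat, threshold = 0.4) {
    stopifnot(threshold >= 0, length(lincValues) == ncol(codingMat))
    if (stats::sd(lincValues) == 0) {
        return(list(rho = setNames(rep(NA_real_, nrow(codingMat)),
                                   rownames(codingMat)),
                    coexpressed = data.frame(gene = character(),
                                             rho = numeric(),
                                             sign = character()),
                    degenerate = TRUE))
    }
    rx <- rank(lincValues)
    ry <- t(apply(codingMat, 1, rank))
    rho <- suppressWarnings(as.vector(stats::cor(rx, t(ry))))
    names(rho) <- rownames(codingMat)
    ## small slack so an exact-boundary rho is not lost to rounding
    hit <- which(!is.na(rho) & abs(rho) >= threshold - 1e-12)
    list(rho = rho,
         coexpressed = data.frame(
             gene = names(rho)[hit],
             rho = unname(rho[hit]),
             sign = ifelse(rho[hit] >= 0, "positive", "negative"),
             stringsAsFactors = FALSE),
         degenerate = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric p per set (overlap at least as large as
#' observed, drawing |query| genes from the universe), BH-adjusted across
#' sets; significant at BH p <= 0.05 by convention.
#'
#' @param query character gene set (subset of \code{universe}).
#' @param sets named list of character vectors (e.g. from \code{readGmt});
#'   each set is intersected with the universe.
#' @param universe character background gene set.
#' @return data.frame: \code{set}, \code{set_size}, \code{overlap},
#'   \code{p_raw}, \code{p_bh}, ordered by \code{p_raw}.
#' @export
hypergeomEnrichment <- function(query, sets, universe) {
    if (!length(universe)) stop("empty universe")
    universe <- unique(universe)
    query <- unique(intersect(query, universe))
    if (!all(query %in% universe)) stop("query must be within the universe")
    N <- length(universe)
    n <- length(query)
    res <- lapply(names(sets), function(nm) {
        s <- intersect(sets[[nm]], universe)
        K <- length(s)
        k <- length(intersect(s, query))
        p <- if (K == 0) 1 else
            stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(set = nm, set_size = K, overlap = k, p_raw = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$p_bh <- bhAdjust(out$p_raw)
    out[order(out$p_raw), , drop = FALSE]
}
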