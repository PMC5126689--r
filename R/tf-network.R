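## TF-lincRNA bipartite network from ChIP-seq peaks: a lincRNA is bound by
## a TF when a peak of that TF falls within the window from 2 kb upstream of
## the lincRNA's TSS through its TES.

#' Promoter-plus-body window of a feature
#'
#' 2 kb (by default) upstream of the transcription start site through the
#' transcription end site, strand-aware: on + the window is
#' [start - upstream, end]; on - it is [start, end + upstream]; clipped at
#' position 1.
#'
#' @param features \code{GRanges}.
#' @param upstream bp added upstream of the TSS.
#' @return \code{GRanges} of windows (strand preserved).
#' @export
promoterBodyWindow <- function(features, upstream = 2000) {
    out <- features
    plus <- as.character(strand(features)) != "-"
    start(out)[plus] <- pmax(1, start(features)[plus] - upstream)
    end(out)[!plus] <- end(features)[!plus] + upstream
    out
}

#' Build the TF-lincRNA bipartite network
#'
#' An edge (TF, lincRNA) exists iff at least one peak of the TF overlaps the
#' lincRNA's promoter-plus-body window by >= 1 bp; peaks are unstranded so
#' the overlap is strand-agnostic. Multiple peaks in one window collapse to
#' one edge.
#'
#' @param lincs \code{GRanges} lincRNA catalog (mcol \code{feature_id}).
#' @param peaks \code{GRanges} with mcol \code{tf}, or a named list of
#'   \code{GRanges} per TF.
#' @param upstream window extension upstream of the TSS, bp.
#' @return \code{BipartiteNetwork}
#' @export
assignEdges <- function(lincs, peaks, upstream = 2000) {
    if (is.list(peaks)) {
        tfs <- rep(names(peaks), lengths(peaks))
        peaks <- do.call(c, unname(peaks))
        mcols(peaks)$tf <- tfs
    }
    win <- promoterBodyWindow(lincs, upstream)
    hits <- findOverlaps(peaks, win, ignore.strand = TRUE)
    edges <- unique(data.frame(
        tf = mcols(peaks)$tf[queryHits(hits)],
        linc = mcols(lincs)$feature_id[subjectHits(hits)],
        stringsAsFactors = FALSE))
    rownames(edges) <- NULL
    new("BipartiteNetwork",
        tfNodes = sort(unique(mcols(peaks)$tf)),
        lincNodes = mcols(lincs)$feature_id,
        edges = edges)
}

#' Key transcription factors by degree
#'
#' TFs binding at least \code{minDegree} distinct lincRNAs.
#'
#' @param network \code{BipartiteNetwork}.
#' @param minDegree inclusive degree cutoff.
#' @return character vector of TF names.
#' @export
keyTFs <- function(network, minDegree = 5) {
    deg <- networkDegree(network)[network@tfNodes]
    names(deg)[deg >= minDegree]
}

#' Differentially expressed transcription factors
#'
#' Significant iff |log2FC| >= \code{fcMinLog2} (default 0.585, a 1.5-fold
#' change) and BH-adjusted p < \code{pMax}.
#'
#' @param tfDe data.frame with columns \code{tf}, \code{log2fc}, \code{p_bh}.
#' @param fcMinLog2 inclusive cutoff on |log2FC|.
#' @param pMax exclusive cutoff on BH-adjusted p.
#' @return character vector of significant TF names.
#' @export
tfDeFilter <- function(tfDe, fcMinLog2 = 0.585, pMax = 0.01) {
    stopifnot(all(c("tf", "log2fc", "p_bh") %in% colnames(tfDe)))
    tfDe$tf[abs(tfDe$log2fc) >= fcMinLog2 & tfDe$p_bh < pMax]
}
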