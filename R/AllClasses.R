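#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Ground truth of a simulated cohort
#'
#' Records every quantity planted by the synthetic-data generators so that
#' downstream stages can be scored against it: per-feature planted log2 fold
#' changes, the latent correlation given to designated divergent (head-to-head)
#' lincRNA/coding-gene pairs, the planted TF-binding edge list, the group
#' hazard ratio of the survival generator, and the seed that determines all of
#' them.
#'
#' @slot log2fc named numeric, planted tumor-vs-normal log2 fold change per
#'   feature (0 for null features).
#' @slot deFeatures character, ids of features with a non-zero planted effect.
#' @slot neighborRho numeric scalar, target correlation for designated
#'   neighbor pairs on the log-expression scale.
#' @slot tfEdges data.frame with columns \code{tf} and \code{linc}, the
#'   planted binding pairs.
#' @slot survivalHR numeric scalar, hazard ratio between high and low
#'   expression groups.
#' @slot seed integer seed that fully determines the simulated outputs.
#'
#' @export
setClass("SimulationTruth", representation(
    log2fc      = "numeric",
    deFeatures  = "character",
    neighborRho = "numeric",
    tfEdges     = "data.frame",
    survivalHR  = "numeric",
    seed        = "integer"
))

setValidity("SimulationTruth", function(object) {
    msg <- character()
    if (length(object@log2fc) && is.null(names(object@log2fc)))
        msg <- c(msg, "log2fc must be named by feature id")
    if (!all(object@deFeatures %in% names(object@log2fc)))
        msg <- c(msg, "every DE feature must carry a log2fc entry")
    if (length(object@neighborRho) != 1 ||
        object@neighborRho < -1 || object@neighborRho > 1)
        msg <- c(msg, "neighborRho must be a single value in [-1, 1]")
    if (nrow(object@tfEdges) &&
        !all(c("tf", "linc") %in% colnames(object@tfEdges)))
        msg <- c(msg, "tfEdges needs columns 'tf' and 'linc'")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulationTruth compact display
#' @param object a \code{SimulationTruth}
#' @export
setMethod("show", "SimulationTruth", function(object) {
    cat("SimulationTruth\n",
        "  planted DE features: ", length(object@deFeatures),
        " of ", length(object@log2fc), "\n",
        "  neighbor rho: ", object@neighborRho, "\n",
        "  TF edges: ", nrow(object@tfEdges), "\n",
        "  survival HR: ", object@survivalHR, "\n",
        "  seed: ", object@seed, "\n", sep = "")
})

#' Permutation-based FDR curve
#'
#' Holds, for a grid of thresholds \code{d} on the absolute test statistic,
#' the observed exceedance count, the mean permuted exceedance count over
#' \code{B} within-pair label permutations, and the resulting FDR estimate
#' (capped at 1 and monotonized from large \code{d} downward).
#'
#' @slot d numeric grid of thresholds on |statistic|.
#' @slot rObs integer, number of observed |statistic| >= d.
#' @slot rPermMean numeric, mean permuted exceedance count at d.
#' @slot fdr numeric, estimated FDR at d (NA where rObs is 0).
#' @slot B integer, number of permutations.
#' @slot seed integer seed used for the permutations.
#'
#' @export
setClass("PermutationFDR", representation(
    d         = "numeric",
    rObs      = "integer",
    rPermMean = "numeric",
    fdr       = "numeric",
    B         = "integer",
    seed      = "integer"
))

setValidity("PermutationFDR", function(object) {
    n <- length(object@d)
    msg <- character()
    if (length(object@rObs) != n || length(object@rPermMean) != n ||
        length(object@fdr) != n)
        msg <- c(msg, "d, rObs, rPermMean and fdr must have equal length")
    ok <- !is.na(object@fdr)
    if (any(object@fdr[ok] < 0 | object@fdr[ok] > 1))
        msg <- c(msg, "fdr must lie in [0, 1]")
    if (is.unsorted(object@d))
        msg <- c(msg, "threshold grid d must be non-decreasing")
    if (length(msg)) msg else TRUE
})

#' @describeIn PermutationFDR compact display
#' @param object a \code{PermutationFDR}
#' @export
setMethod("show", "PermutationFDR", function(object) {
    cat("PermutationFDR (B = ", object@B, ", seed = ", object@seed, ")\n",
        "  ", length(object@d), " thresholds, |stat| in [",
        round(min(object@d), 3), ", ", round(max(object@d), 3), "]\n",
        sep = "")
    ok <- which(!is.na(object@fdr) & object@fdr < 0.01)
    if (length(ok)) {
        cat("  smallest d with FDR < 1%: ", round(object@d[min(ok)], 3),
            " (", object@rObs[min(ok)], " features)\n", sep = "")
    } else {
        cat("  no threshold reaches FDR < 1%\n")
    }
})

#' TF-lincRNA bipartite network
#'
#' A bipartite graph with transcription factors on one side and lincRNAs on
#' the other; an edge means at least one ChIP-seq peak of the TF falls in the
#' lincRNA's promoter-plus-body window (2 kb upstream of the TSS through the
#' TES). Multiple peaks in one window collapse to a single edge.
#'
#' @slot tfNodes character, all TFs offered to the builder (including
#'   degree-0 ones).
#' @slot lincNodes character, all lincRNAs offered to the builder.
#' @slot edges data.frame with columns \code{tf} and \code{linc}, one row per
#'   distinct pair.
#'
#' @export
setClass("BipartiteNetwork", representation(
    tfNodes   = "character",
    lincNodes = "character",
    edges     = "data.frame"
))

setValidity("BipartiteNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("tf", "linc") %in% colnames(e)))
        msg <- c(msg, "edges needs columns 'tf' and 'linc'")
    else {
        if (!all(e$tf %in% object@tfNodes))
            msg <- c(msg, "edge TF not in tfNodes")
        if (!all(e$linc %in% object@lincNodes))
            msg <- c(msg, "edge lincRNA not in lincNodes")
        if (anyDuplicated(paste(e$tf, e$linc, sep = "\r")))
            msg <- c(msg, "duplicate edges are not allowed")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn BipartiteNetwork compact display
#' @param object a \code{BipartiteNetwork}
#' @export
setMethod("show", "BipartiteNetwork", function(object) {
    deg <- networkDegree(object)
    connected <- sum(deg[object@lincNodes] > 0)
    cat("BipartiteNetwork\n",
        "  ", length(object@tfNodes), " TFs, ",
        length(object@lincNodes), " lincRNAs, ",
        nrow(object@edges), " edges\n",
        "  lincRNAs bound by >= 1 TF: ", connected, "\n", sep = "")
})

#' Node degrees of a bipartite network
#'
#' @param network a \code{BipartiteNetwork}
#' @return named integer vector over all TF and lincRNA nodes; degree counts
#'   distinct partners only.
#' @export
networkDegree <- function(network) {
    stopifnot(is(network, "BipartiteNetwork"))
    nodes <- c(network@tfNodes, network@lincNodes)
    deg <- integer(length(nodes))
    names(deg) <- nodes
    if (nrow(network@edges)) {
        td <- table(network@edges$tf)
        ld <- table(network@edges$linc)
        deg[names(td)] <- as.integer(td)
        deg[names(ld)] <- as.integer(ld)
    }
    deg
}

#' Edge list accessor
#'
#' @param network a \code{BipartiteNetwork}
#' @return data.frame with columns \code{tf}, \code{linc}
#' @export
networkEdges <- function(network) {
    stopifnot(is(network, "BipartiteNetwork"))
    network@edges
}
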