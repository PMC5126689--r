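## lincRNA catalog construction: transcript-level filters, isoform
## collapsing, and the expression calling-rate filter.

#' Filter assembled transcripts against a known lincRNA catalog
#'
#' A transcript is kept iff (i) its locus overlaps a known lincRNA by at
#' least 1 bp (strand-agnostic), (ii) its length is at least \code{minLen}
#' nt (transcripts shorter than 200 nt are removed), and (iii) its
#' noncoding score is at least \code{codingCutoff} (transcripts scoring
#' below 0.5 are classified as coding and removed; scores near 1 indicate
#' noncoding). Transcripts with a missing score are kept with a warning.
#'
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{parent_linc_id}, \code{chrom}, \code{start}, \code{end} (1-based
#'   closed), \code{length} (summed exon length, nt) and optional
#'   \code{coding_score} in [0, 1].
#' @param known \code{GRanges} catalog of known lincRNAs.
#' @param minLen minimum transcript length, nt.
#' @param codingCutoff noncoding-score cutoff; below it the transcript is
#'   removed.
#' @return the kept rows of \code{transcripts}; per-filter rejection counts
#'   in \code{attr(, "rejected")}.
#' @export
filterTranscripts <- function(transcripts, known, minLen = 200,
                              codingCutoff = 0.5) {
    if (length(known) == 0) stop("known lincRNA catalog is empty")
    loci <- GRanges(transcripts$chrom,
                    IRanges(transcripts$start, transcripts$end))
    overlaps <- IRanges::overlapsAny(loci, known, ignore.strand = TRUE)
    longEnough <- transcripts$length >= minLen
    score <- if ("coding_score" %in% colnames(transcripts))
        transcripts$coding_score else rep(NA_real_, nrow(transcripts))
    if (any(!is.na(score) & (score < 0 | score > 1)))
        stop("coding_score outside [0, 1]")
    noncoding <- is.na(score) | score >= codingCutoff
    if (any(is.na(score)))
        warning(sum(is.na(score)),
                " transcript(s) without coding score kept by policy")
    keep <- overlaps & longEnough & noncoding
    out <- transcripts[keep, , drop = FALSE]
    attr(out, "rejected") <- c(no_overlap = sum(!overlaps),
                               too_short = sum(!longEnough),
                               coding = sum(!noncoding))
    out
}

#' Collapse isoforms to per-lincRNA values
#'
#' When two or more transcripts map to one lincRNA locus, the locus is
#' assigned the arithmetic mean of its isoforms' values, column-wise.
#'
#' @param values numeric matrix (or data.frame) of per-transcript values
#'   (e.g. FPKM per sample, or a single coverage column).
#' @param parent character vector of parent lincRNA ids, one per row.
#' @return matrix with one row per parent id (mean over isoforms), rows
#'   ordered by first appearance of the parent.
#' @export
collapseIsoforms <- function(values, parent) {
    values <- as.matrix(values)
    stopifnot(nrow(values) == length(parent), nrow(values) >= 1)
    sums <- rowsum(values, group = parent, reorder = FALSE)
    sizes <- as.vector(table(factor(parent, levels = rownames(sums))))
    sums / sizes
}

#' Expression calling-rate filter
#'
#' A feature is called expressed in a sample when its FPKM is at or above
#' \code{fpkmCall} (0.3, the detectability threshold above background); it is
#' kept when the calling rate -- the fraction of samples in which it is
#' called -- is at or above \code{minRate} (20%). Both comparisons are
#' inclusive.
#'
#' @param se \code{SummarizedExperiment} with an FPKM assay, or a numeric
#'   matrix.
#' @param fpkmCall detection threshold on FPKM.
#' @param minRate minimum calling rate in [0, 1].
#' @return list: \code{kept} (character feature ids) and \code{profile}
#'   (data.frame: \code{feature_id}, \code{n_called}, \code{n_samples},
#'   \code{calling_rate}, \code{kept}).
#' @export
callingRateFilter <- function(se, fpkmCall = 0.3, minRate = 0.20) {
    mat <- if (is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, 1L) else as.matrix(se)
    if (ncol(mat) == 0) stop("no samples in matrix")
    nCalled <- rowSums(mat >= fpkmCall)
    rate <- nCalled / ncol(mat)
    kept <- rate >= minRate
    profile <- data.frame(feature_id = rownames(mat),
                          n_called = as.integer(nCalled),
                          n_samples = ncol(mat),
                          calling_rate = rate,
                          kept = kept,
                          stringsAsFactors = FALSE, row.names = NULL)
    list(kept = rownames(mat)[kept], profile = profile)
}
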