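#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   mcols mcols<- reduce findOverlaps distance resize flank strand<- start<-
#'   end<-
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom GenomeInfoDb seqlevels seqnames<-
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom utils read.delim write.table
NULL

## Interval convention: everything inside the package is a GRanges, i.e.
## 1-based closed coordinates; rtracklayer does the GTF/BED arithmetic on
## read/write so no manual off-by-one handling exists anywhere.

#' Read gene annotation from GTF
#'
#' Imports a GTF (GENCODE dialect: \code{gene_id}, \code{gene_type}/
#' \code{gene_biotype} attributes), collapses records to gene level as the
#' union span of all records sharing a \code{gene_id} (min start, max end),
#' and returns one stranded range per gene. Biotypes other than
#' \code{lincRNA} and \code{protein_coding} are kept as \code{"other"}.
#'
#' @param path GTF file path.
#' @param biotypeFilter optional character vector; when given, only genes
#'   whose biotype is in the set are returned.
#' @return \code{GRanges} with mcols \code{feature_id} and \code{biotype};
#'   names are feature ids.
#' @export
readGtf <- function(path, biotypeFilter = NULL) {
    gr <- rtracklayer::import(path, format = "gtf")
    if (length(gr) == 0) {
        warning("empty GTF: ", path)
        out <- GRanges()
        mcols(out)$feature_id <- character()
        mcols(out)$biotype <- character()
        return(out)
    }
    m <- mcols(gr)
    ids <- as.character(m$gene_id)
    if (all(is.na(ids)) || is.null(m$gene_id))
        stop("GTF has no gene_id attribute: ", path)
    bt <- if (!is.null(m$gene_type)) as.character(m$gene_type)
          else if (!is.null(m$gene_biotype)) as.character(m$gene_biotype)
          else rep(NA_character_, length(gr))
    nostrand <- as.character(strand(gr)) == "*"
    if (any(nostrand)) {
        warning(sum(nostrand), " GTF record(s) without strand rejected")
        gr <- gr[!nostrand]; ids <- ids[!nostrand]; bt <- bt[!nostrand]
    }
    ## gene-level union span per gene_id
    first <- !duplicated(ids)
    sp <- split(seq_along(gr), ids)[unique(ids)]
    st <- vapply(sp, function(i) min(start(gr)[i]), numeric(1))
    en <- vapply(sp, function(i) max(end(gr)[i]), numeric(1))
    idx <- vapply(sp, `[`, numeric(1), 1L)
    out <- GRanges(seqnames(gr)[idx], IRanges(st, en), strand = strand(gr)[idx])
    biotype <- bt[idx]
    biotype[!biotype %in% c("lincRNA", "protein_coding") | is.na(biotype)] <-
        "other"
    mcols(out)$feature_id <- ids[idx]
    mcols(out)$biotype <- biotype
    names(out) <- ids[idx]
    if (!is.null(biotypeFilter))
        out <- out[mcols(out)$biotype %in% biotypeFilter]
    out
}

#' Write a gene catalog as GTF
#'
#' One \code{gene} record per feature; round-trips \code{readGtf} coordinates
#' exactly.
#'
#' @param catalog \code{GRanges} with mcols \code{feature_id}, \code{biotype}.
#' @param path output path.
#' @export
writeGtf <- function(catalog, path) {
    gr <- granges(catalog)
    mcols(gr)$source <- "lincSignature"
    mcols(gr)$type <- "gene"
    mcols(gr)$gene_id <- mcols(catalog)$feature_id
    mcols(gr)$gene_type <- mcols(catalog)$biotype
    rtracklayer::export(gr, path, format = "gtf")
    invisible(path)
}

#' Read ChIP-seq peaks from BED
#'
#' BED3+ input; rows with non-positive width are rejected with a warning.
#'
#' @param path BED file path.
#' @param tfName transcription-factor name attached to every peak.
#' @return \code{GRanges} with mcol \code{tf}.
#' @export
readBed <- function(path, tfName) {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    if (!length(ln)) return(GRanges(tf = character()))
    parts <- strsplit(ln, "\t", fixed = TRUE)
    chrom <- vapply(parts, `[`, character(1), 1L)
    s0 <- as.numeric(vapply(parts, `[`, character(1), 2L))
    e0 <- as.numeric(vapply(parts, `[`, character(1), 3L))
    bad <- !is.finite(s0) | !is.finite(e0) | s0 >= e0
    if (any(bad))
        warning(sum(bad), " BED record(s) with start >= end rejected in ",
                basename(path))
    gr <- GRanges(chrom[!bad], IRanges(s0[!bad] + 1, e0[!bad]))
    mcols(gr)$tf <- rep(tfName, length(gr))
    gr
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix is a TSV whose first column holds feature ids and whose header
#' row holds sample ids; the sheet is a TSV with at least \code{sample_id}
#' and \code{tissue} (\code{tumor}/\code{adjacent}/\code{normal}), optionally
#' \code{pair_id}, \code{er_status}, \code{batch}, \code{age}, \code{race}.
#' Samples present in the matrix but absent from the sheet are a hard error,
#' as are negative values, and non-integer values when \code{unit="counts"}.
#'
#' @param path matrix TSV path.
#' @param sheetPath sample sheet TSV path.
#' @param unit \code{"FPKM"} or \code{"counts"}.
#' @return \code{SummarizedExperiment} with one assay named after the unit
#'   (lower case) and the sheet as \code{colData}.
#' @export
readExpression <- function(path, sheetPath, unit = c("FPKM", "counts")) {
    unit <- match.arg(unit)
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- as.character(tab[[1]])
    storage.mode(mat) <- "double"
    if (anyNA(mat)) stop("missing values in expression matrix: ", path)
    if (any(mat < 0)) stop("negative values in expression matrix: ", path)
    if (unit == "counts" && any(mat != round(mat)))
        stop("counts matrix contains non-integer values: ", path)
    sheet <- readSampleSheet(sheetPath)
    missing <- setdiff(colnames(mat), sheet$sample_id)
    if (length(missing))
        stop("sample(s) absent from sample sheet: ",
             paste(missing, collapse = ", "))
    sheet <- sheet[match(colnames(mat), sheet$sample_id), , drop = FALSE]
    assays <- list(mat)
    names(assays) <- tolower(unit)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = DataFrame(sheet, row.names = sheet$sample_id))
    S4Vectors::metadata(se)$unit <- unit
    se
}

#' Read a sample sheet TSV
#'
#' @param path TSV with columns \code{sample_id}, \code{tissue} and optional
#'   clinical columns.
#' @return data.frame
#' @export
readSampleSheet <- function(path) {
    sheet <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "tissue")
    if (!all(need %in% colnames(sheet)))
        stop("sample sheet must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(sheet$sample_id))
        stop("duplicate sample_id in sheet: ", path)
    bad <- !sheet$tissue %in% c("tumor", "adjacent", "normal")
    if (any(bad))
        stop("unknown tissue label(s): ",
             paste(unique(sheet$tissue[bad]), collapse = ", "))
    if ("pair_id" %in% colnames(sheet)) {
        pp <- sheet[!is.na(sheet$pair_id) & sheet$pair_id != "", ]
        ok <- tapply(pp$tissue, pp$pair_id, function(tt)
            sum(tt == "tumor") == 1 && sum(tt == "adjacent") == 1)
        if (length(ok) && !all(ok))
            stop("each pair_id must label exactly one tumor and one adjacent sample")
    }
    sheet
}

#' Write an expression matrix and sample sheet
#'
#' Counts round-trip bit-exactly; FPKM is written with enough digits to
#' round-trip to at least 6 significant figures.
#'
#' @param se \code{SummarizedExperiment} from \code{readExpression} or a
#'   simulator.
#' @param path matrix TSV path.
#' @param sheetPath optional sample sheet TSV path.
#' @export
writeExpression <- function(se, path, sheetPath = NULL) {
    mat <- SummarizedExperiment::assay(se, 1L)
    df <- data.frame(feature_id = rownames(mat),
                     format(mat, digits = 9, trim = TRUE, scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sheetPath)) {
        write.table(as.data.frame(SummarizedExperiment::colData(se)),
                    sheetPath, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read gene sets from GMT
#'
#' @param path GMT path: per line, set name, description, then member ids,
#'   tab-separated.
#' @return named list of character vectors; descriptions in
#'   \code{attr(, "description")}.
#' @export
readGmt <- function(path) {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    parts <- strsplit(ln, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3
    if (any(bad)) {
        warning(sum(bad), " GMT line(s) with fewer than 3 fields skipped")
        parts <- parts[!bad]
    }
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[`, character(1), 1L)
    attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
    sets
}

#' Default analysis configuration
#'
#' Every threshold of the pipeline in one auditable list: transcript filters
#' (\code{min_len}, \code{coding_cutoff}), expression calling
#' (\code{fpkm_call}, \code{min_calling_rate}), discovery selection
#' (\code{fc_min}, \code{bh_max}, \code{fdr_max}, \code{n_permutations}),
#' replication (\code{rep_fc_min_log2}, \code{rep_fc_min_log2_relaxed},
#' \code{rep_p_max}), network (\code{promoter_upstream},
#' \code{key_tf_min_degree}, \code{tf_fc_min_log2}, \code{tf_p_max}),
#' neighbor analysis (\code{non_neighbor_gap}, \code{n_random_pairs}),
#' function inference (\code{rho_min}, \code{n_shuffles},
#' \code{enrich_p_max}) and survival (\code{survival_p_max}).
#'
#' @return named list of defaults.
#' @export
defaultConfig <- function() {
    list(
        min_len            = 200,
        coding_cutoff      = 0.5,
        fpkm_call          = 0.3,
        min_calling_rate   = 0.20,
        fc_min             = 2,
        bh_max             = 0.01,
        fdr_max            = 0.01,
        n_permutations     = 1000L,
        rep_fc_min_log2    = 1,
        rep_fc_min_log2_relaxed = 0.585,
        rep_p_max          = 0.05,
        promoter_upstream  = 2000,
        key_tf_min_degree  = 5L,
        tf_fc_min_log2     = 0.585,
        tf_p_max           = 0.01,
        non_neighbor_gap   = 1e6,
        n_random_pairs     = 1000L,
        rho_min            = 0.4,
        n_shuffles         = 1000L,
        enrich_p_max       = 0.05,
        survival_p_max     = 0.05
    )
}

#' Read / write the run configuration
#'
#' YAML round-trip of the threshold list; unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return named list merged over \code{defaultConfig()}.
#' @export
readConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    def <- defaultConfig()
    unknown <- setdiff(names(cfg), names(def))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    def[names(cfg)] <- cfg
    def
}

#' @rdname readConfig
#' @param config named list as from \code{defaultConfig()}.
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}
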