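## End-to-end orchestration on synthetic data. Stages communicate only
## through files under the run directory, so each stage can be re-run in
## isolation; one master seed expands into fixed per-stage offsets.

stageSeed <- function(seed, k) (as.integer(seed) + 1000L * k) %% 2147483647L

#' Run the full pipeline on a simulated cohort
#'
#' Simulates annotation, FPKM and count cohorts, TF peaks and survival;
#' then runs catalog filtering, discovery DE with the permutation FDR,
#' replication testing, network construction, neighbor co-expression,
#' function inference, and clinical association -- writing every stage
#' output as a plain-text file under \code{outDir} and returning a summary
#' report. A stage failure is recorded in the report and later stages that
#' do not depend on it still run.
#'
#' @param outDir run directory (created).
#' @param seed master seed; per-stage seeds are fixed offsets of it.
#' @param config threshold list from \code{defaultConfig()}.
#' @param nLinc,nCoding,nPairs,nRepPairs,nControls cohort dimensions.
#' @param B permutations for the FDR stage.
#' @param nTFs number of simulated transcription factors.
#' @param simulate when FALSE, skip the simulation stage and consume the
#'   files already present under \code{outDir} (each analysis stage reads
#'   only files, so a broken input fails its stage in isolation).
#' @return list with per-stage counts, output paths, seeds, and
#'   \code{failed} (character vector of failed stage names).
#' @export
runAll <- function(outDir, seed = 1L, config = defaultConfig(),
                   nLinc = 40, nCoding = 80, nPairs = 20, nRepPairs = 20,
                   nControls = 10, B = 200, nTFs = 6, simulate = TRUE) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    report <- list(seed = seed, failed = character(), counts = list())
    fail <- function(stage, e) {
        warning("stage ", stage, " failed: ", conditionMessage(e))
        report$failed <<- c(report$failed, stage)
    }

    ## -- simulate ------------------------------------------------------
    if (simulate) {
    ann <- simulateAnnotation(nLinc, nCoding, seed = stageSeed(seed, 1L))
    writeGtf(ann$catalog, file.path(outDir, "annotation.gtf"))
    write.table(ann$pairs, file.path(outDir, "designated_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fpkm <- simulateFpkmCohort(ann, nPairs = nPairs,
                               seed = stageSeed(seed, 2L))
    writeExpression(fpkm$se, file.path(outDir, "fpkm.tsv"),
                    file.path(outDir, "fpkm_sheet.tsv"))
    cnt <- simulateCountCohort(ann, nPairs = nRepPairs,
                               nControls = nControls, truth = fpkm$truth,
                               seed = stageSeed(seed, 3L))
    writeExpression(cnt$se, file.path(outDir, "counts.tsv"),
                    file.path(outDir, "counts_sheet.tsv"))
    tfs <- sprintf("TF%02d", seq_len(nTFs))
    lincIds <- ann$pairs$linc
    edges <- withSeed(stageSeed(seed, 4L), {
        do.call(rbind, lapply(tfs, function(tf) data.frame(
            tf = tf,
            linc = sample(lincIds, max(2, rpois(1, 5))),
            stringsAsFactors = FALSE)))
    })
    edges <- unique(edges)
    peaks <- simulatePeaks(ann, edges, jitter = 0,
                           seed = stageSeed(seed, 5L))
    writePeakBeds(peaks, file.path(outDir, "peaks"))
    jsonlite::write_json(
        list(de_features = fpkm$truth@deFeatures,
             log2fc = as.list(fpkm$truth@log2fc[fpkm$truth@deFeatures]),
             tf_edges = edges, seed = seed),
        file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }

    ## -- annotate (calling-rate filter) --------------------------------
    catalog <- readGtf(file.path(outDir, "annotation.gtf"))
    fpkmSe <- readExpression(file.path(outDir, "fpkm.tsv"),
                             file.path(outDir, "fpkm_sheet.tsv"), "FPKM")
    lincCat <- catalog[mcols(catalog)$biotype == "lincRNA"]
    cr <- callingRateFilter(
        SummarizedExperiment::assay(fpkmSe)[names(lincCat), , drop = FALSE],
        config$fpkm_call, config$min_calling_rate)
    write.table(cr$profile, file.path(outDir, "calling_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    keptLincs <- lincCat[cr$kept]
    report$counts$lincs_kept <- length(keptLincs)

    ## -- discovery DE --------------------------------------------------
    de <- discoveryDE(fpkmSe)
    pf <- permutationFdr(fpkmSe, B = B, seed = stageSeed(seed, 6L))
    selected <- tryCatch(
        suppressWarnings(selectDE(de, pf, config$fc_min, config$bh_max,
                                  config$fdr_max)),
        error = function(e) character())
    selected <- intersect(selected, names(keptLincs))
    de$selected <- de$feature_id %in% selected
    write.table(de, file.path(outDir, "discovery_de.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(
        data.frame(d = pf@d, r_obs = pf@rObs, r_perm_mean = pf@rPermMean,
                   fdr = pf@fdr),
        file.path(outDir, "permutation_fdr.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    report$counts$de_selected <- length(selected)

    ## -- replication DE ------------------------------------------------
    tryCatch({
        cntSe <- readExpression(file.path(outDir, "counts.tsv"),
                                file.path(outDir, "counts_sheet.tsv"),
                                "counts")
        paired <- nbTest(cntSe, c("tumor", "adjacent"),
                         covariates = c("age", "race", "batch"))
        tvn <- nbTest(cntSe, c("tumor", "normal"),
                      covariates = c("age", "race"))
        write.table(paired, file.path(outDir, "replication_paired.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(tvn, file.path(outDir, "replication_tvn.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        disc <- de[de$selected, c("feature_id", "log2fc")]
        verdict <- replicationFilter(
            disc,
            data.frame(feature_id = paired$feature_id,
                       log2fc = paired$log2fc, p = paired$p_raw),
            data.frame(feature_id = tvn$feature_id,
                       log2fc = tvn$log2fc, p = tvn$p_raw),
            config$rep_fc_min_log2, config$rep_p_max)
        write.table(verdict, file.path(outDir, "replication_verdict.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        report$counts$replicated <- sum(verdict$passes_paired, na.rm = TRUE)
    }, error = function(e) fail("replication", e))

    ## -- TF network ----------------------------------------------------
    tryCatch({
        bedFiles <- list.files(file.path(outDir, "peaks"),
                               pattern = "\\.bed$", full.names = TRUE)
        if (!length(bedFiles)) stop("no peak files found")
        peakList <- lapply(bedFiles, function(f)
            readBed(f, sub("\\.bed$", "", basename(f))))
        names(peakList) <- sub("\\.bed$", "", basename(bedFiles))
        net <- assignEdges(lincCat, peakList, config$promoter_upstream)
        write.table(networkEdges(net), file.path(outDir, "network_edges.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        report$counts$network_edges <- nrow(networkEdges(net))
        report$counts$key_tfs <- length(keyTFs(net, config$key_tf_min_degree))
    }, error = function(e) fail("network", e))

    ## -- neighbor co-expression ----------------------------------------
    tryCatch({
        genes <- catalog[mcols(catalog)$biotype == "protein_coding"]
        nb <- nearestCodingGene(lincCat, genes)
        adjSamples <- rownames(SummarizedExperiment::colData(fpkmSe))[
            SummarizedExperiment::colData(fpkmSe)$tissue == "adjacent"]
        nb <- pairwiseSpearman(fpkmSe, nb, adjSamples)
        write.table(nb, file.path(outDir, "neighbor_pairs.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        report$counts$pairs_by_orientation <- table(nb$orientation)
        p0 <- mean(nb$orientation == "H2H")
        if (length(selected) && p0 > 0 && p0 < 1) {
            deNb <- nb[nb$linc %in% selected, ]
            report$counts$h2h_p <- h2hEnrichment(
                sum(deNb$orientation == "H2H"), nrow(deNb), p0)
        }
    }, error = function(e) fail("neighbors", e))

    ## -- function inference --------------------------------------------
    tryCatch({
        genes <- catalog[mcols(catalog)$biotype == "protein_coding"]
        mat <- SummarizedExperiment::assay(fpkmSe)
        codingMat <- mat[names(genes), , drop = FALSE]
        target <- if (length(selected)) selected[1]
                  else mcols(lincCat)$feature_id[1]
        cs <- coexpressedSet(mat[target, ], codingMat, config$rho_min)
        ## gene sets built from the annotation (per-chromosome blocks)
        sets <- split(names(genes), as.character(seqnames(genes)))
        enr <- hypergeomEnrichment(cs$coexpressed$gene, sets, names(genes))
        write.table(enr, file.path(outDir, "enrichment.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        report$counts$coexpressed_genes <- nrow(cs$coexpressed)
        report$counts$enriched_sets <- sum(enr$p_bh <= config$enrich_p_max)
    }, error = function(e) fail("function", e))

    ## -- clinical ------------------------------------------------------
    tryCatch({
        surv <- simulateSurvival(n = max(4, 2 * nPairs), hr = 2,
                                 censorRate = 0.2,
                                 seed = stageSeed(seed, 7L))
        write.table(surv, file.path(outDir, "survival.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        lr <- logrankTest(surv$time, surv$event, surv$group)
        hz <- hazardRatio(surv$time, surv$event, surv$group)
        report$counts$survival_logrank_p <- lr$p
        report$counts$survival_hr <- hz$hr
    }, error = function(e) fail("clinical", e))

    report$outDir <- outDir
    saveReport <- report
    saveReport$counts <- lapply(report$counts, function(x)
        if (is.table(x)) as.list(x) else x)
    jsonlite::write_json(saveReport, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    report
}
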