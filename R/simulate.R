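## Synthetic cohorts with recorded ground truth. The generators emulate the
## statistical structure the analysis assumes -- paired FPKM matrices with
## sparse, low-level lincRNA expression and planted log2 fold changes; NB
## count matrices with unequal library sizes; TF peaks planted in promoter
## windows; divergent-pair co-expression via a shared latent factor;
## exponential survival with a known group hazard ratio -- so that every
## downstream stage can be scored against known truth.

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
    force(expr)
}

## Largest-remainder apportionment of n among proportions p (sums to n).
apportion <- function(n, p) {
    p <- p / sum(p)
    raw <- n * p
    k <- floor(raw)
    rem <- n - sum(k)
    if (rem > 0) {
        o <- order(raw - k, decreasing = TRUE)
        k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
    }
    as.integer(k)
}

#' Simulate a lincRNA / protein-coding annotation with designated neighbors
#'
#' Places each lincRNA with a nearest protein-coding partner at a log-uniform
#' gap (200 bp to 100 kb) in a requested transcriptional orientation
#' (\code{H2H} divergent, \code{H2T} same-strand, \code{T2T} convergent);
#' remaining coding genes are decoys placed more than 1 Mb from everything.
#' Each lincRNA/partner pair occupies its own 3 Mb block so the designated
#' partner is provably the nearest coding gene.
#'
#' @param nLinc number of lincRNAs.
#' @param nCoding number of protein-coding genes (\code{>= nLinc}; the excess
#'   become decoys).
#' @param orientationMix named proportions over \code{c("H2H","H2T","T2T")};
#'   allocated by largest remainder so counts are deterministic.
#' @param seed integer seed.
#' @return list with \code{catalog} (GRanges, mcols \code{feature_id},
#'   \code{biotype}) and \code{pairs} (data.frame: \code{linc}, \code{gene},
#'   \code{orientation}, \code{distance}).
#' @export
simulateAnnotation <- function(nLinc = 50, nCoding = 100,
                               orientationMix = c(H2H = 1, H2T = 1, T2T = 1) / 3,
                               seed = 1L) {
    stopifnot(nLinc >= 1, nCoding >= nLinc,
              all(names(orientationMix) %in% c("H2H", "H2T", "T2T")),
              abs(sum(orientationMix) - 1) < 1e-8 || sum(orientationMix) > 0)
    nBlocks <- nCoding          # one block per pair or decoy
    blockSize <- 3e6
    perChrom <- 80L
    chroms <- paste0("chr", seq_len(ceiling(nBlocks / perChrom)))
    if (length(chroms) > 23)
        stop("chromosome capacity exceeded; use fewer features")
    counts <- apportion(nLinc, orientationMix[c("H2H", "H2T", "T2T")])
    orientation <- rep(c("H2H", "H2T", "T2T"), counts)
    withSeed(seed, {
        orientation <- sample(orientation)
        wl <- round(runif(nLinc, 1000, 20000))
        wg <- round(runif(nCoding, 5000, 50000))
        gap <- round(exp(runif(nLinc, log(200), log(1e5))))
        lincIds <- sprintf("LINC%04d", seq_len(nLinc))
        geneIds <- sprintf("GENE%04d", seq_len(nCoding))
        block <- seq_len(nBlocks) - 1L
        chr <- chroms[block %/% perChrom + 1L]
        base <- (block %% perChrom) * blockSize + 50000
        ls <- le <- gs <- ge <- numeric(nLinc)
        lstr <- gstr <- character(nLinc)
        for (i in seq_len(nLinc)) {
            ls[i] <- base[i]; le[i] <- base[i] + wl[i] - 1
            gs[i] <- le[i] + gap[i] + 1; ge[i] <- gs[i] + wg[i] - 1
            ori <- orientation[i]
            if (ori == "H2H") { lstr[i] <- "-"; gstr[i] <- "+" }
            else if (ori == "H2T") { lstr[i] <- "+"; gstr[i] <- "+" }
            else { lstr[i] <- "+"; gstr[i] <- "-" }
        }
        decoy <- seq(nLinc + 1L, length.out = nCoding - nLinc)
        catalog <- GRanges(
            c(chr[seq_len(nLinc)], chr[seq_len(nLinc)], chr[decoy]),
            IRanges(c(ls, gs, base[decoy]),
                    c(le, ge, base[decoy] + wg[decoy] - 1)),
            strand = c(lstr, gstr,
                       sample(c("+", "-"), length(decoy), replace = TRUE)))
        ids <- c(lincIds, geneIds)
        mcols(catalog)$feature_id <- ids
        mcols(catalog)$biotype <- c(rep("lincRNA", nLinc),
                                    rep("protein_coding", nCoding))
        names(catalog) <- ids
        list(catalog = catalog,
             pairs = data.frame(linc = lincIds,
                                gene = geneIds[seq_len(nLinc)],
                                orientation = orientation,
                                distance = gap,
                                stringsAsFactors = FALSE))
    })
}

## Build the planted-truth object shared by the expression generators.
makeTruth <- function(featureIds, lincIds, deFraction, log2fcMagnitude,
                      probDown, neighborRho, seed) {
    lfc <- setNames(numeric(length(featureIds)), featureIds)
    nDE <- round(deFraction * length(lincIds))
    de <- character()
    if (nDE > 0) {
        de <- sample(lincIds, nDE)
        sgn <- ifelse(runif(nDE) < probDown, -1, 1)
        lfc[de] <- sgn * log2fcMagnitude
    }
    new("SimulationTruth", log2fc = lfc, deFeatures = de,
        neighborRho = neighborRho, tfEdges = data.frame(tf = character(),
                                                        linc = character()),
        survivalHR = 1, seed = as.integer(seed))
}

#' Simulate a paired FPKM cohort
#'
#' Tumor/adjacent pairs with log-normal baselines (lincRNAs low: meanlog
#' log 2, sdlog 1.2; coding genes higher: meanlog log 20, sdlog 1),
#' multiplicative log-normal sample noise (sdlog 0.4), planted tumor-vs-normal
#' log2 fold changes on a fraction of lincRNAs, dropout zeros on lincRNA rows,
#' and a shared per-sample latent factor for designated divergent neighbor
#' pairs tuned to a target log-scale correlation. The coding partner of a
#' planted-DE lincRNA in a designated pair inherits the planted effect scaled
#' by \code{neighborRho}, so fold-change concordance is planted along with
#' expression correlation.
#'
#' @param annotation output of \code{simulateAnnotation}.
#' @param nPairs number of tumor/adjacent pairs (>= 3).
#' @param deFraction fraction of lincRNAs given a planted effect.
#' @param log2fcMagnitude absolute planted log2 fold change.
#' @param probDown probability a planted effect is a down-regulation.
#' @param neighborRho target correlation for designated neighbor pairs.
#' @param sparsity dropout probability for lincRNA entries, in [0, 1).
#' @param truth optional \code{SimulationTruth} to reuse (e.g. to give a
#'   replication cohort the same planted effects); when supplied the
#'   planted-effect parameters are ignored.
#' @param seed integer seed.
#' @return list with \code{se} (SummarizedExperiment, assay \code{fpkm},
#'   colData sample sheet) and \code{truth} (\code{SimulationTruth}).
#' @export
simulateFpkmCohort <- function(annotation, nPairs = 85, deFraction = 0.1,
                               log2fcMagnitude = 3, probDown = 0.7,
                               neighborRho = 0.5, sparsity = 0.1,
                               truth = NULL, seed = 1L) {
    if (nPairs < 3) stop("nPairs must be at least 3")
    stopifnot(sparsity >= 0, sparsity < 1)
    catalog <- annotation$catalog
    ids <- mcols(catalog)$feature_id
    isLinc <- mcols(catalog)$biotype == "lincRNA"
    nFeat <- length(ids)
    withSeed(seed, {
        if (is.null(truth))
            truth <- makeTruth(ids, ids[isLinc], deFraction, log2fcMagnitude,
                               probDown, neighborRho, seed)
        else neighborRho <- truth@neighborRho
        lfc <- truth@log2fc
        ## partner genes of designated pairs inherit a scaled effect
        pr <- annotation$pairs
        hit <- pr$linc %in% truth@deFeatures
        lfc[pr$gene[hit]] <- lfc[pr$linc[hit]] * neighborRho
        truth@log2fc <- lfc
        baseMu <- ifelse(isLinc, log(2), log(20))
        baseSd <- ifelse(isLinc, 1.2, 1.0)
        baseline <- exp(rnorm(nFeat, baseMu, baseSd))
        names(baseline) <- ids
        nSamp <- 2L * nPairs
        sdNoise <- 0.4
        logx <- matrix(rnorm(nFeat * nSamp, 0, sdNoise), nFeat, nSamp)
        ## shared latent factor per designated pair and sample
        if (neighborRho > 0 && nrow(pr)) {
            b <- sdNoise * sqrt(neighborRho / (1 - neighborRho))
            z <- matrix(rnorm(nrow(pr) * nSamp), nrow(pr), nSamp)
            iL <- match(pr$linc, ids); iG <- match(pr$gene, ids)
            logx[iL, ] <- logx[iL, ] + b * z
            logx[iG, ] <- logx[iG, ] + b * z
            ## rescale so total sd stays sdNoise-comparable (not required for
            ## rank correlation, kept for effect-size stability)
        }
        tumorCol <- rep(c(TRUE, FALSE), nPairs)
        mat <- baseline * exp(logx)
        mat[, tumorCol] <- mat[, tumorCol] * 2^lfc
        if (sparsity > 0) {
            drop <- matrix(runif(sum(isLinc) * nSamp) < sparsity,
                           sum(isLinc), nSamp)
            sub <- mat[isLinc, , drop = FALSE]
            sub[drop] <- 0
            mat[isLinc, ] <- sub
        }
        pairIds <- sprintf("P%03d", rep(seq_len(nPairs), each = 2))
        sampleIds <- paste0(pairIds, c("_T", "_A"))
        er <- rep(sample(c("ER+", "ER-"), nPairs, replace = TRUE,
                         prob = c(0.78, 0.22)), each = 2)
        sheet <- data.frame(
            sample_id = sampleIds,
            tissue = rep(c("tumor", "adjacent"), nPairs),
            pair_id = pairIds,
            er_status = er,
            batch = "B1",
            age = round(rep(rnorm(nPairs, 57, 13), each = 2), 1),
            race = rep(sample(c("White", "Black", "Asian"), nPairs,
                              replace = TRUE, prob = c(0.85, 0.1, 0.05)),
                       each = 2),
            stringsAsFactors = FALSE)
        colnames(mat) <- sampleIds
        rownames(mat) <- ids
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(fpkm = mat),
            rowRanges = catalog,
            colData = DataFrame(sheet, row.names = sampleIds))
        S4Vectors::metadata(se)$unit <- "FPKM"
        list(se = se, truth = truth)
    })
}

#' Simulate a negative-binomial count cohort
#'
#' Replication-style design: paired tumor/adjacent cases plus unpaired
#' healthy-normal controls. Counts are drawn NB with mean = library size x
#' relative abundance x 2^(planted log2FC for tumor samples) and variance
#' mu + dispersion * mu^2; library sizes are uniform over
#' \code{libsizeRange}; batch, age and race labels are assigned at random.
#'
#' @param annotation output of \code{simulateAnnotation}.
#' @param nPairs tumor/adjacent pairs.
#' @param nControls healthy-normal samples.
#' @param deFraction,log2fcMagnitude,probDown planted-effect parameters as in
#'   \code{simulateFpkmCohort}.
#' @param dispersion NB dispersion phi (> 0); variance is mu + phi mu^2.
#' @param libsizeRange length-2 numeric, library-size bounds.
#' @param truth optional \code{SimulationTruth} to reuse; when supplied the
#'   planted-effect parameters are ignored.
#' @param seed integer seed.
#' @return list with \code{se} (assay \code{counts}) and \code{truth}.
#' @export
simulateCountCohort <- function(annotation, nPairs = 50, nControls = 23,
                                deFraction = 0.1, log2fcMagnitude = 3,
                                probDown = 0.7, dispersion = 0.2,
                                libsizeRange = c(5e5, 2e6), truth = NULL,
                                seed = 1L) {
    stopifnot(dispersion > 0, nPairs >= 2)
    catalog <- annotation$catalog
    ids <- mcols(catalog)$feature_id
    isLinc <- mcols(catalog)$biotype == "lincRNA"
    nFeat <- length(ids)
    withSeed(seed, {
        if (is.null(truth))
            truth <- makeTruth(ids, ids[isLinc], deFraction, log2fcMagnitude,
                               probDown, 0, seed)
        lfc <- truth@log2fc
        ra <- exp(rnorm(nFeat, ifelse(isLinc, log(2), log(20)), 1))
        ra <- ra / sum(ra)
        nSamp <- 2L * nPairs + nControls
        lib <- runif(nSamp, libsizeRange[1], libsizeRange[2])
        tissue <- c(rep(c("tumor", "adjacent"), nPairs),
                    rep("normal", nControls))
        mu <- outer(ra, lib)
        mu[, tissue == "tumor"] <- mu[, tissue == "tumor"] * 2^lfc
        counts <- matrix(rnbinom(nFeat * nSamp, mu = mu,
                                 size = 1 / dispersion), nFeat, nSamp)
        pairIds <- c(sprintf("RP%03d", rep(seq_len(nPairs), each = 2)),
                     rep(NA_character_, nControls))
        sampleIds <- c(paste0(pairIds[seq_len(2 * nPairs)], c("_T", "_A")),
                       sprintf("CTRL%03d", seq_len(nControls)))
        age <- numeric(nSamp)
        age[tissue != "normal"] <- rep(round(rnorm(nPairs, 52, 11), 1),
                                       each = 2)
        age[tissue == "normal"] <- round(rnorm(nControls, 52, 11), 1)
        race <- character(nSamp)
        race[tissue != "normal"] <- rep(
            sample(c("White", "Black"), nPairs, replace = TRUE,
                   prob = c(0.78, 0.22)), each = 2)
        race[tissue == "normal"] <- sample(c("White", "Black"), nControls,
                                           replace = TRUE, prob = c(0.78, 0.22))
        sheet <- data.frame(
            sample_id = sampleIds, tissue = tissue, pair_id = pairIds,
            er_status = NA_character_,
            batch = sample(c("B1", "B2"), nSamp, replace = TRUE),
            age = age, race = race, stringsAsFactors = FALSE)
        dimnames(counts) <- list(ids, sampleIds)
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            rowRanges = catalog,
            colData = DataFrame(sheet, row.names = sampleIds))
        S4Vectors::metadata(se)$unit <- "counts"
        list(se = se, truth = truth)
    })
}

#' Simulate TF ChIP-seq peaks for a planted edge list
#'
#' Each planted (TF, lincRNA) edge yields one peak of width 300 bp centered
#' 1 kb upstream of the lincRNA TSS (inside the promoter-plus-body window),
#' jittered uniformly by at most \code{jitter} bp. For every TF, lincRNAs
#' without a planted edge optionally receive a decoy peak at least 10 kb
#' outside the window.
#'
#' @param annotation output of \code{simulateAnnotation}.
#' @param tfEdges data.frame with columns \code{tf}, \code{linc}.
#' @param jitter maximum absolute displacement of the peak center, bp.
#' @param decoys emit decoy peaks for non-edges of each TF.
#' @param seed integer seed.
#' @return \code{GRanges} of peaks with mcol \code{tf}.
#' @export
simulatePeaks <- function(annotation, tfEdges, jitter = 0, decoys = TRUE,
                          seed = 1L) {
    stopifnot(jitter >= 0, all(c("tf", "linc") %in% colnames(tfEdges)))
    catalog <- annotation$catalog
    lincs <- catalog[mcols(catalog)$biotype == "lincRNA"]
    halfW <- 150
    withSeed(seed, {
        peaks <- GRanges()
        for (k in seq_len(nrow(tfEdges))) {
            g <- lincs[tfEdges$linc[k]]
            tss <- if (as.character(strand(g)) == "+") start(g) else end(g)
            center <- if (as.character(strand(g)) == "+") tss - 1000
                      else tss + 1000
            if (jitter > 0) center <- center + round(runif(1, -jitter, jitter))
            p <- GRanges(seqnames(g), IRanges(center - halfW, center + halfW))
            mcols(p)$tf <- tfEdges$tf[k]
            peaks <- c(peaks, p)
        }
        if (decoys) {
            for (tf in unique(tfEdges$tf)) {
                out <- setdiff(names(lincs),
                               tfEdges$linc[tfEdges$tf == tf])
                for (id in out) {
                    g <- lincs[id]
                    w <- promoterBodyWindow(g)
                    center <- start(w) - 10000 - halfW - 1
                    p <- GRanges(seqnames(g),
                                 IRanges(center - halfW, center + halfW))
                    mcols(p)$tf <- tf
                    peaks <- c(peaks, p)
                }
            }
        }
        peaks
    })
}

#' Write peaks to per-TF BED files
#'
#' @param peaks \code{GRanges} with mcol \code{tf}.
#' @param dir output directory (created if absent); one
#'   \code{<TF>.bed} per TF, BED3 0-based half-open.
#' @return invisible vector of written paths.
#' @export
writePeakBeds <- function(peaks, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character()
    for (tf in unique(mcols(peaks)$tf)) {
        p <- peaks[mcols(peaks)$tf == tf]
        df <- data.frame(as.character(seqnames(p)), start(p) - 1L, end(p))
        path <- file.path(dir, paste0(tf, ".bed"))
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        paths <- c(paths, path)
    }
    invisible(paths)
}

#' Simulate survival with a known group hazard ratio
#'
#' Exponential event times with rate \code{baseRate} in the low group and
#' \code{baseRate * hr} in the high group; independent exponential censoring
#' with rate solved so the expected censored fraction equals
#' \code{censorRate}.
#'
#' @param n subjects (split evenly high/low).
#' @param hr hazard ratio, high vs low group.
#' @param censorRate expected fraction censored, in [0, 1).
#' @param baseRate event rate in the low group.
#' @param seed integer seed.
#' @return data.frame: \code{subject_id}, \code{time}, \code{event} (1 event,
#'   0 censored), \code{group} (\code{high}/\code{low}).
#' @export
simulateSurvival <- function(n = 400, hr = 2, censorRate = 0.2,
                             baseRate = 0.1, seed = 1L) {
    stopifnot(censorRate >= 0, censorRate < 1, hr > 0, n >= 4)
    withSeed(seed, {
        nHigh <- n %/% 2
        group <- c(rep("high", nHigh), rep("low", n - nHigh))
        rate <- ifelse(group == "high", baseRate * hr, baseRate)
        tt <- rexp(n, rate)
        if (censorRate > 0) {
            cc <- rexp(n, rate * censorRate / (1 - censorRate))
            event <- as.integer(tt <= cc)
            tt <- pmin(tt, cc)
        } else {
            event <- rep(1L, n)
        }
        data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                   time = tt, event = event, group = group,
                   stringsAsFactors = FALSE)
    })
}
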