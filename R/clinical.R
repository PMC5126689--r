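## Clinical association: median-split grouping, Kaplan-Meier curves,
## log-rank comparison and the univariate hazard ratio (all survival
## machinery via the survival package), plus the ER-subtype specificity
## comparison.

#' Median split of expression values
#'
#' Values strictly above the median go to \code{high}; values at or below
#' the median (ties included) go to \code{low}.
#'
#' @param values numeric vector, one entry per patient (names kept).
#' @return character vector in \code{c("high", "low")}.
#' @export
medianSplit <- function(values) {
    stopifnot(length(values) >= 2)
    if (length(unique(values)) == 1)
        stop("all expression values identical; no median split possible")
    med <- stats::median(values)
    out <- ifelse(values > med, "high", "low")
    names(out) <- names(values)
    out
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator; subjects censored at an event time are counted
#' at risk at that time and removed after.
#'
#' @param time,event numeric vectors (event 1 = event, 0 = censored).
#' @param group optional grouping vector.
#' @return data.frame: \code{group}, \code{time}, \code{n_risk},
#'   \code{n_event}, \code{survival}, one row per distinct event/censoring
#'   time per group.
#' @export
kmEstimate <- function(time, event, group = NULL) {
    if (is.null(group)) group <- rep("all", length(time))
    fit <- survival::survfit(survival::Surv(time, event) ~ group)
    sm <- summary(fit, censored = TRUE)
    grp <- if (is.null(sm$strata)) rep(unique(group), length(sm$time))
           else sub("^group=", "", as.character(sm$strata))
    data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
               n_event = sm$n.event, survival = sm$surv,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Log-rank test between two survival groups
#'
#' @param time,event numeric vectors.
#' @param group two-level grouping vector.
#' @return list: \code{chi2}, \code{p} (NA when no events at risk in
#'   common).
#' @export
logrankTest <- function(time, event, group) {
    if (sum(event) == 0) stop("log-rank needs at least one event")
    fit <- try(survival::survdiff(survival::Surv(time, event) ~ group),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(list(chi2 = NA_real_, p = NA_real_))
    list(chi2 = unname(fit$chisq),
         p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate hazard ratio of high vs low expression
#'
#' Cox proportional-hazards partial likelihood with Breslow tie handling;
#' the confidence interval comes from the observed information. A monotone
#' likelihood (all events in one group first) yields an infinite estimate
#' with a flag.
#'
#' @param time,event numeric vectors.
#' @param group vector with levels \code{low} (reference) and \code{high}.
#' @return list: \code{hr}, \code{ci} (length 2), \code{p} (Wald),
#'   \code{monotone} flag.
#' @export
hazardRatio <- function(time, event, group) {
    group <- factor(group, levels = c("low", "high"))
    if (any(table(group[event == 1]) == 0) && sum(event) > 0) {
        ## no events in one arm: partial likelihood is monotone
        fit <- suppressWarnings(
            survival::coxph(survival::Surv(time, event) ~ group,
                            ties = "breslow"))
        return(list(hr = unname(exp(stats::coef(fit))), ci = c(NA, NA),
                    p = NA_real_, monotone = TRUE))
    }
    fit <- survival::coxph(survival::Surv(time, event) ~ group,
                           ties = "breslow",
                           control = survival::coxph.control(eps = 1e-9))
    s <- summary(fit)
    list(hr = unname(s$conf.int[1, "exp(coef)"]),
         ci = unname(s$conf.int[1, c("lower .95", "upper .95")]),
         p = unname(s$coefficients[1, "Pr(>|z|)"]),
         monotone = !is.finite(s$coefficients[1, "se(coef)"]) ||
             s$coefficients[1, "se(coef)"] > 100)
}

#' Median-split survival screen over features
#'
#' For each feature: split patients at the median expression, run the
#' log-rank test and the univariate Cox hazard ratio of high vs low.
#'
#' @param exprMat numeric matrix, features x patients.
#' @param time,event numeric vectors aligned with the columns.
#' @return data.frame: \code{feature_id}, \code{hr}, \code{logrank_p},
#'   \code{wald_p}, \code{median_high}, \code{median_low}.
#' @export
survivalScreen <- function(exprMat, time, event) {
    stopifnot(ncol(exprMat) == length(time), length(time) == length(event))
    res <- lapply(rownames(exprMat), function(id) {
        v <- exprMat[id, ]
        grp <- tryCatch(medianSplit(v), error = function(e) NULL)
        if (is.null(grp) || length(unique(grp)) < 2 || sum(event) == 0)
            return(data.frame(feature_id = id, hr = NA_real_,
                              logrank_p = NA_real_, wald_p = NA_real_,
                              median_high = NA_real_, median_low = NA_real_,
                              stringsAsFactors = FALSE))
        lr <- logrankTest(time, event, grp)
        hz <- hazardRatio(time, event, grp)
        data.frame(feature_id = id, hr = hz$hr, logrank_p = lr$p,
                   wald_p = hz$p,
                   median_high = stats::median(v[grp == "high"]),
                   median_low = stats::median(v[grp == "low"]),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' ER-subtype specificity comparison
#'
#' Per feature, unpaired Wilcoxon rank-sum tests of ER+ tumors against ER-
#' tumors and against normal samples, with mean-based log2 fold changes and
#' BH adjustment within each contrast. A feature is flagged ER+-specific
#' when both contrasts pass |log2FC| >= \code{fcMinLog2} and BH p <
#' \code{pMax}.
#'
#' @param se expression \code{SummarizedExperiment}; colData needs
#'   \code{tissue} and \code{er_status}.
#' @param fcMinLog2,pMax flag thresholds.
#' @return data.frame: \code{feature_id}, per-contrast \code{log2fc} /
#'   \code{p_bh}, and \code{er_specific}.
#' @export
subtypeCompare <- function(se, fcMinLog2 = 1, pMax = 0.05) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    mat <- SummarizedExperiment::assay(se, 1L)
    erPos <- which(cd$tissue == "tumor" & cd$er_status %in% "ER+")
    erNeg <- which(cd$tissue == "tumor" & cd$er_status %in% "ER-")
    normal <- which(cd$tissue %in% c("adjacent", "normal"))
    if (length(erPos) < 3 || length(erNeg) < 3 || length(normal) < 3)
        stop("each class (ER+, ER-, normal) needs at least 3 samples")
    oneContrast <- function(a, b) {
        p <- apply(mat, 1, function(x)
            suppressWarnings(stats::wilcox.test(x[a], x[b])$p.value))
        lfc <- log2((rowMeans(mat[, a, drop = FALSE]) + 0.1) /
                    (rowMeans(mat[, b, drop = FALSE]) + 0.1))
        data.frame(log2fc = lfc, p_bh = bhAdjust(p))
    }
    c1 <- oneContrast(erPos, erNeg)
    c2 <- oneContrast(erPos, normal)
    pass <- function(cc) abs(cc$log2fc) >= fcMinLog2 & cc$p_bh < pMax
    data.frame(feature_id = rownames(mat),
               log2fc_pos_vs_neg = c1$log2fc, p_bh_pos_vs_neg = c1$p_bh,
               log2fc_pos_vs_normal = c2$log2fc,
               p_bh_pos_vs_normal = c2$p_bh,
               er_specific = pass(c1) & pass(c2) & c1$log2fc > 0 &
                   c2$log2fc > 0,
               stringsAsFactors = FALSE, row.names = NULL)
}
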