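# Negative-binomial Wald differential expression with trended moment
# dispersion. Used for subgroup-versus-rest comparisons and, with a
# patient-blocked design, for the paired tube comparison. This is a
# deliberately transparent NB-Wald implementation: per-gene moment
# dispersion estimates are shrunk toward a lowess mean-dispersion trend and
# the Wald statistic is referred to a t distribution on the residual
# degrees of freedom.

# per-gene moment dispersion around a fitted Poisson mean, then lowess
# trend shrinkage on the log scale
.trendedDispersions <- function(counts, X, sf) {
    n <- ncol(counts)
    p <- qr(X)$rank
    df <- max(1L, n - p)
    off <- log(sf)
    raw <- numeric(nrow(counts))
    baseMean <- numeric(nrow(counts))
    for (g in seq_len(nrow(counts))) {
        k <- counts[g, ]
        fit <- suppressWarnings(glm.fit(X, k, family = stats::poisson(),
                                        offset = off))
        mu <- pmax(fit$fitted.values, 1e-8)
        raw[g] <- sum(((k - mu)^2 - mu) / mu^2) / df
        baseMean[g] <- mean(k / sf)
    }
    # trend fitted on the raw (possibly negative) moment estimates so the
    # sampling noise averages out instead of biasing the trend low
    rawClamped <- pmin(pmax(raw, 0), 10)
    use <- baseMean > 0
    trend <- rep(NA_real_, length(raw))
    if (sum(use) >= 10) {
        lx <- log(baseMean[use])
        ly <- pmin(raw[use], 10)
        ord <- order(lx)
        fit <- lowess(lx[ord], ly[ord], f = 0.5)
        trend[use] <- pmax(approx(fit$x, fit$y, xout = lx, rule = 2,
                                  ties = mean)$y, 1e-8)
    } else {
        trend[use] <- pmax(mean(pmin(raw[use], 10)), 1e-8)
    }
    w <- df / (df + 20)
    disp <- w * rawClamped + (1 - w) * trend
    disp[!use] <- NA_real_
    list(dispersion = pmin(pmax(disp, 1e-8), 10), baseMean = baseMean)
}

# NB GLM Wald test on one coefficient of a design matrix
.nbWald <- function(counts, X, sf, coefIndex) {
    disp <- .trendedDispersions(counts, X, sf)
    n <- ncol(counts)
    dfResid <- max(1L, n - qr(X)$rank)
    off <- log(sf)
    est <- se <- rep(NA_real_, nrow(counts))
    for (g in seq_len(nrow(counts))) {
        a <- disp$dispersion[g]
        if (is.na(a)) next
        fam <- MASS::negative.binomial(theta = 1 / a)
        fit <- tryCatch(
            suppressWarnings(glm.fit(X, counts[g, ], family = fam,
                                     offset = off)),
            error = function(e) NULL)
        if (is.null(fit) || fit$rank < ncol(X)) next
        pr <- fit$rank
        Rmat <- qr.R(fit$qr)[seq_len(pr), seq_len(pr), drop = FALSE]
        cov <- tryCatch(chol2inv(Rmat), error = function(e) NULL)
        if (is.null(cov)) next
        piv <- fit$qr$pivot[seq_len(pr)]
        pos <- match(coefIndex, piv)
        if (is.na(pos)) next
        est[g] <- fit$coefficients[coefIndex]
        se[g] <- sqrt(cov[pos, pos])
    }
    tstat <- est / se
    pval <- 2 * pt(-abs(tstat), df = dfResid)
    data.frame(gene = rownames(counts),
               baseMean = disp$baseMean,
               log2FoldChange = est / log(2),
               lfcSE = se / log(2),
               stat = tstat,
               pvalue = pval,
               padj = p.adjust(pval, method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Subgroup-versus-rest differential expression
#'
#' Negative-binomial Wald test of one group against all other samples:
#' median-of-ratios size factors, per-gene moment dispersion shrunk toward
#' a lowess mean-dispersion trend, and a log-link NB GLM whose group
#' coefficient is the log2 fold change (group over rest). P-values are
#' BH-adjusted.
#'
#' @param counts Count matrix (genes x samples) or SummarizedExperiment.
#' @param groupMask Logical vector, TRUE for the foreground group.
#' @param minMeanCount Genes whose mean raw count is at or below this are
#'   excluded (default 0: all-zero genes drop out).
#' @param factors Optional size factors.
#' @return data.frame with \code{gene}, \code{baseMean},
#'   \code{log2FoldChange}, \code{lfcSE}, \code{stat}, \code{pvalue},
#'   \code{padj}; excluded genes are absent.
#' @export
differentialExpression <- function(counts, groupMask, minMeanCount = 0,
                                   factors = NULL) {
    m <- .asCountMatrix(counts)
    groupMask <- as.logical(groupMask)
    if (length(groupMask) != ncol(m))
        stop("'groupMask' must have one entry per sample", call. = FALSE)
    if (!any(groupMask) || all(groupMask))
        stop("both groups must be non-empty", call. = FALSE)
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
    keep <- rowMeans(m) > minMeanCount
    m <- m[keep, , drop = FALSE]
    if (is.null(factors)) factors <- sizeFactors(m)
    X <- cbind(1, as.numeric(groupMask))
    .nbWald(m, X, factors, coefIndex = 2L)
}

#' Paired (patient-blocked) differential expression
#'
#' The paired tube comparison: an NB GLM with free per-patient intercepts
#' and a single condition coefficient, so the condition effect is estimated
#' within patients. Genes with mean raw count at or below
#' \code{minMeanCount} (default 10) are excluded. The reported log2 fold
#' change is \code{condition} over \code{reference}.
#'
#' @param counts Count matrix (genes x samples) or SummarizedExperiment.
#' @param design data.frame with \code{patient} and \code{condition}
#'   columns, one row per sample in column order (for a
#'   SummarizedExperiment, colData is used when \code{design} is missing).
#' @param reference Reference condition level (default \code{"EDTA"}, so
#'   effects read PAXgene versus EDTA).
#' @param minMeanCount Mean-count exclusion threshold (strictly greater
#'   than; default 10).
#' @return data.frame as in [differentialExpression()].
#' @export
pairedDifferentialExpression <- function(counts, design = NULL,
                                         reference = "EDTA",
                                         minMeanCount = 10) {
    if (is(counts, "SummarizedExperiment") && is.null(design))
        design <- as.data.frame(SummarizedExperiment::colData(counts))
    m <- .asCountMatrix(counts)
    .requireColumns(design, c("patient", "condition"), "paired design")
    if (nrow(design) != ncol(m))
        stop("design must have one row per sample", call. = FALSE)
    tab <- table(design$patient, design$condition)
    if (ncol(tab) != 2L)
        stop("exactly two conditions are required", call. = FALSE)
    bad <- rownames(tab)[apply(tab, 1L, function(x) any(x != 1L))]
    if (length(bad))
        stop("unpaired patient(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    if (length(unique(design$patient)) < 2L)
        stop("at least 2 patients are required", call. = FALSE)
    if (!reference %in% design$condition)
        stop(sprintf("reference condition '%s' not present", reference),
             call. = FALSE)
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
    keep <- rowMeans(m) > minMeanCount
    m <- m[keep, , drop = FALSE]
    factors <- sizeFactors(m)
    patient <- factor(design$patient)
    condition <- factor(design$condition,
                        levels = c(reference,
                                   setdiff(unique(design$condition),
                                           reference)))
    X <- stats::model.matrix(~ patient + condition)
    .nbWald(m, X, factors, coefIndex = ncol(X))
}
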