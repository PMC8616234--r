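# Differential isoform usage (subgroup versus rest) and cross-set
# direction concordance.

#' Differential isoform usage, subgroup versus rest
#'
#' Per isoform, usage (isoform count / gene total) is compared between the
#' foreground group and the rest with an overdispersed (quasi-binomial)
#' logistic regression on per-sample proportions weighted by gene totals.
#' Genes need at least two isoforms and a total count of at least
#' \code{minGeneCount} in at least half of the samples; single-isoform
#' genes are excluded and listed. Direction is the sign of (group usage -
#' rest usage); q-values are BH over all tested isoforms.
#'
#' @param isoCounts Isoform count matrix (isoforms x samples).
#' @param isoToGene data.frame with \code{isoform_id}, \code{gene_id}.
#' @param groupMask Logical per-sample foreground indicator.
#' @param minGeneCount Minimum gene total per sample (default 10).
#' @return A list with \code{results} (data.frame \code{isoform_id},
#'   \code{gene_id}, \code{delta_proportion}, \code{direction},
#'   \code{pvalue}, \code{qvalue}) and \code{excluded} (data.frame of
#'   excluded genes with reasons).
#' @export
differentialIsoformUsage <- function(isoCounts, isoToGene, groupMask,
                                     minGeneCount = 10) {
    m <- .asCountMatrix(isoCounts)
    .requireColumns(isoToGene, c("isoform_id", "gene_id"),
                    "isoform-to-gene map")
    groupMask <- as.logical(groupMask)
    if (length(groupMask) != ncol(m))
        stop("'groupMask' must have one entry per sample", call. = FALSE)
    if (!any(groupMask) || all(groupMask))
        stop("both groups must be non-empty", call. = FALSE)
    if (is.null(rownames(m)))
        stop("'isoCounts' must have isoform_id rownames", call. = FALSE)
    map <- isoToGene[match(rownames(m), isoToGene$isoform_id), ]
    if (anyNA(map$gene_id))
        stop("isoform(s) missing from the map", call. = FALSE)

    geneTotals <- rowsum(m, map$gene_id)
    nIso <- table(map$gene_id)
    excluded <- list()
    testable <- character()
    for (g in rownames(geneTotals)) {
        if (nIso[[g]] < 2L) {
            excluded[[g]] <- "single_isoform"
        } else if (mean(geneTotals[g, ] >= minGeneCount) < 0.5) {
            excluded[[g]] <- "low_count"
        } else testable <- c(testable, g)
    }

    rows <- list()
    for (g in testable) {
        tot <- geneTotals[g, ]
        ok <- tot > 0
        if (sum(ok & groupMask) < 2L || sum(ok & !groupMask) < 2L) {
            excluded[[g]] <- "insufficient_samples"
            next
        }
        isoIdx <- which(map$gene_id == g)
        for (i in isoIdx) {
            y <- m[i, ok]
            n <- tot[ok]
            grp <- as.numeric(groupMask[ok])
            prop <- y / n
            fit <- tryCatch(suppressWarnings(
                glm(prop ~ grp, family = stats::quasibinomial(),
                    weights = n)),
                error = function(e) NULL)
            pv <- NA_real_
            if (!is.null(fit) && !is.na(coef(fit)[2])) {
                sm <- summary(fit)$coefficients
                if (nrow(sm) >= 2L) pv <- sm[2, 4]
            }
            pg <- sum(y[grp == 1]) / sum(n[grp == 1])
            pr <- sum(y[grp == 0]) / sum(n[grp == 0])
            rows[[length(rows) + 1L]] <- data.frame(
                isoform_id = rownames(m)[i], gene_id = g,
                delta_proportion = pg - pr,
                direction = sign(pg - pr),
                pvalue = pv, stringsAsFactors = FALSE)
        }
    }
    res <- if (length(rows)) do.call(rbind, rows) else
        data.frame(isoform_id = character(), gene_id = character(),
                   delta_proportion = numeric(), direction = numeric(),
                   pvalue = numeric(), stringsAsFactors = FALSE)
    res$qvalue <- p.adjust(res$pvalue, method = "BH")
    exc <- data.frame(gene_id = names(excluded),
                      reason = unlist(excluded, use.names = FALSE),
                      stringsAsFactors = FALSE)
    list(results = res, excluded = exc)
}

#' Direction concordance between two isoform-usage result sets
#'
#' Shared isoforms are those present in both tables with q below
#' \code{looseQ} in both; among them, \code{nSignificantShared} counts
#' those with q below \code{strictQ} in both, and direction concordance is
#' the fraction with equal usage-change sign. With no shared isoforms the
#' concordance is reported as undefined (NA with \code{defined = FALSE}),
#' not zero.
#'
#' @param setA,setB Result data.frames from
#'   [differentialIsoformUsage()] (the \code{results} element).
#' @param looseQ Loose q threshold defining presence (default 1.0).
#' @param strictQ Strict significance threshold (default 0.05).
#' @return A list with \code{nShared}, \code{nSignificantShared},
#'   \code{directionConcordance}, \code{defined} and \code{table} (the
#'   per-isoform comparison).
#' @examples
#' a <- data.frame(isoform_id = c("i1", "i2"), direction = c(1, -1),
#'                 qvalue = c(0.01, 0.2))
#' usageConcordance(a, a)$directionConcordance  # 1
#' @export
usageConcordance <- function(setA, setB, looseQ = 1.0, strictQ = 0.05) {
    .requireColumns(setA, c("isoform_id", "direction", "qvalue"), "setA")
    .requireColumns(setB, c("isoform_id", "direction", "qvalue"), "setB")
    a <- setA[!is.na(setA$qvalue) & setA$qvalue < looseQ, ]
    b <- setB[!is.na(setB$qvalue) & setB$qvalue < looseQ, ]
    shared <- intersect(a$isoform_id, b$isoform_id)
    if (!length(shared))
        return(list(nShared = 0L, nSignificantShared = 0L,
                    directionConcordance = NA_real_, defined = FALSE,
                    table = data.frame(isoform_id = character(),
                                       direction_a = numeric(),
                                       direction_b = numeric(),
                                       q_a = numeric(), q_b = numeric(),
                                       concordant = logical())))
    ia <- match(shared, a$isoform_id)
    ib <- match(shared, b$isoform_id)
    tab <- data.frame(
        isoform_id = shared,
        direction_a = a$direction[ia], direction_b = b$direction[ib],
        q_a = a$qvalue[ia], q_b = b$qvalue[ib],
        concordant = a$direction[ia] == b$direction[ib],
        stringsAsFactors = FALSE)
    list(nShared = length(shared),
         nSignificantShared = sum(tab$q_a < strictQ & tab$q_b < strictQ),
         directionConcordance = mean(tab$concordant),
         defined = TRUE, table = tab)
}
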