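# Paired tube-technology comparison: effect-size tiers, rank scores,
# decay-constant correlation, and clustering/PCA diagnostics. (The paired
# differential expression itself lives in de.R.)

#' Effect-size tiers of differential expression results
#'
#' Nested DEG tiers at increasing absolute log2-fold-change cutoffs.
#' Membership in tier i requires q below \code{qThreshold} and
#' \code{|log2FC|} strictly greater than \code{cutoffs[i]}, so tier 3 is a
#' subset of tier 2 is a subset of tier 1.
#'
#' @param results data.frame from [pairedDifferentialExpression()] or
#'   [differentialExpression()].
#' @param cutoffs Increasing |log2FC| cutoffs (default 1, 2, 3).
#' @param qThreshold Significance threshold (default 0.05).
#' @return A list with \code{summary} (data.frame \code{cutoff},
#'   \code{n_total}, \code{n_up}, \code{n_down}) and \code{genes} (list of
#'   per-tier gene vectors).
#' @export
effectSizeTiers <- function(results, cutoffs = c(1, 2, 3),
                            qThreshold = 0.05) {
    .requireColumns(results, c("gene", "log2FoldChange", "padj"),
                    "results")
    sig <- !is.na(results$padj) & results$padj < qThreshold &
        !is.na(results$log2FoldChange)
    genes <- list()
    rows <- lapply(seq_along(cutoffs), function(i) {
        inTier <- sig & abs(results$log2FoldChange) > cutoffs[i]
        genes[[i]] <<- results$gene[inTier]
        data.frame(cutoff = cutoffs[i],
                   n_total = sum(inTier),
                   n_up = sum(inTier & results$log2FoldChange > 0),
                   n_down = sum(inTier & results$log2FoldChange < 0))
    })
    names(genes) <- paste0("tier", seq_along(cutoffs))
    list(summary = do.call(rbind, rows), genes = genes)
}

#' Expression rank score
#'
#' \code{log2FC * (-log10 q)}: the score used to order genes for
#' pre-ranked enrichment. A q of exactly 0 is clamped to the smallest
#' positive double with a warning (the score would otherwise be infinite).
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param q Numeric vector of BH-adjusted q-values in (0, 1].
#' @return Numeric vector of scores.
#' @examples
#' rankScore(2, 0.01)   # 4
#' rankScore(-1, 0.1)   # -1
#' rankScore(3, 1)      # 0
#' @export
rankScore <- function(log2fc, q) {
    if (any(q < 0 | q > 1, na.rm = TRUE))
        stop("q-values must lie in [0, 1]", call. = FALSE)
    if (any(q == 0, na.rm = TRUE)) {
        warning("q-value(s) of 0 clamped to the smallest positive double")
        q[q == 0] <- .Machine$double.xmin
    }
    log2fc * (-log10(q))
}

#' Ranked gene list from differential expression results
#'
#' Genes scored by [rankScore()] and strictly ordered by score descending,
#' ties broken lexicographically by gene name.
#'
#' @param results data.frame with \code{gene}, \code{log2FoldChange},
#'   \code{padj}.
#' @return Named numeric vector of scores, ordered for
#'   [prerankedEnrichment()].
#' @export
rankedGeneList <- function(results) {
    .requireColumns(results, c("gene", "log2FoldChange", "padj"),
                    "results")
    ok <- !is.na(results$log2FoldChange) & !is.na(results$padj)
    res <- results[ok, ]
    scores <- rankScore(res$log2FoldChange, res$padj)
    ord <- order(-scores, res$gene)
    stats::setNames(scores[ord], res$gene[ord])
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then gene symbols.
#'
#' @param path File path.
#' @return Named list of gene-symbol vectors.
#' @export
readGmt <- function(path) {
    fgsea::gmtPathways(path)
}

#' Pre-ranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (weight exponent 1 on
#' the absolute rank score) against a gene-label permutation null, as in
#' classic pre-ranked GSEA; computed by \code{fgsea::fgseaSimple}. Sets are
#' intersected with the ranking universe first; sets outside
#' [\code{minSize}, \code{maxSize}] after intersection are skipped and
#' listed. NES is the enrichment score divided by the mean absolute null
#' score of matching sign; p-values honour the permutation floor and FDR is
#' BH across the tested sets.
#'
#' @param ranking Named numeric vector from [rankedGeneList()].
#' @param geneSets Named list of gene-symbol vectors (see [readGmt()]).
#' @param minSize,maxSize Post-intersection size range (defaults 15, 500).
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A list with \code{results} (data.frame \code{set}, \code{size},
#'   \code{ES}, \code{NES}, \code{pvalue}, \code{fdr}) and \code{skipped}
#'   (data.frame of sets outside the size range).
#' @export
prerankedEnrichment <- function(ranking, geneSets, minSize = 15L,
                                maxSize = 500L, nPerm = 1000L, seed = 1L) {
    if (is.null(names(ranking)))
        stop("'ranking' must be a named score vector", call. = FALSE)
    sizes <- vapply(geneSets, function(s)
        length(intersect(s, names(ranking))), integer(1))
    skip <- sizes < minSize | sizes > maxSize
    skipped <- data.frame(set = names(geneSets)[skip],
                          size = sizes[skip], stringsAsFactors = FALSE)
    set.seed(seed)
    res <- suppressWarnings(fgsea::fgseaSimple(
        pathways = geneSets[!skip], stats = ranking, nperm = nPerm,
        minSize = 1L, maxSize = length(ranking), scoreType = "std",
        nproc = 0))
    out <- data.frame(set = res$pathway, size = res$size, ES = res$ES,
                      NES = res$NES, pvalue = res$pval, fdr = res$padj,
                      stringsAsFactors = FALSE)
    list(results = out[order(out$pvalue, out$set), ], skipped = skipped)
}

#' Transcripts-per-million from counts and gene lengths
#'
#' @param counts Count matrix (genes x samples).
#' @param lengths Per-gene transcript lengths (bp).
#' @return TPM matrix of the same shape.
#' @export
computeTPM <- function(counts, lengths) {
    m <- .asCountMatrix(counts)
    if (length(lengths) != nrow(m))
        stop("'lengths' must have one value per gene", call. = FALSE)
    rate <- m / lengths
    sweep(rate, 2L, colSums(rate), "/") * 1e6
}

#' Correlation of expression with mRNA decay constants
#'
#' Spearman correlation of log TPM (condition means) with per-gene decay
#' constants over the DEG sets, per condition, with the least-squares
#' slope; plus a rank-sum comparison of decay constants between up- and
#' downregulated DEG sets.
#'
#' @param tpm Matrix of per-gene mean TPM per condition (genes x
#'   conditions) or a named vector for a single condition.
#' @param decayConstants Named numeric vector, gene to decay constant.
#' @param upSet,downSet Character vectors of up-/downregulated DEGs.
#' @param minGenes Minimum decay-annotated genes per set (default 10);
#'   below this the comparison is reported as not evaluable.
#' @return A list with \code{correlations} (data.frame \code{condition},
#'   \code{rho}, \code{pvalue}, \code{slope}, \code{n}), \code{comparison}
#'   (list: \code{medianUp}, \code{medianDown}, \code{direction},
#'   \code{pvalue}) and \code{evaluable}.
#' @export
decayCorrelation <- function(tpm, decayConstants, upSet, downSet,
                             minGenes = 10L) {
    if (is.null(names(decayConstants)))
        stop("'decayConstants' must be named by gene", call. = FALSE)
    if (is.vector(tpm)) tpm <- cbind(condition = tpm)
    degs <- unique(c(upSet, downSet))
    genes <- intersect(intersect(degs, rownames(tpm)),
                       names(decayConstants))
    upG <- intersect(upSet, names(decayConstants))
    downG <- intersect(downSet, names(decayConstants))
    if (length(upG) < minGenes || length(downG) < minGenes ||
        length(genes) < minGenes)
        return(list(correlations = NULL, comparison = NULL,
                    evaluable = FALSE))
    cors <- lapply(colnames(tpm), function(cond) {
        x <- log2(tpm[genes, cond] + 1)
        y <- decayConstants[genes]
        ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
        data.frame(condition = cond, rho = unname(ct$estimate),
                   pvalue = ct$p.value,
                   slope = unname(coef(stats::lm(y ~ x))[2]),
                   n = length(genes), stringsAsFactors = FALSE)
    })
    du <- decayConstants[upG]
    dd <- decayConstants[downG]
    wt <- suppressWarnings(wilcox.test(du, dd))
    list(correlations = do.call(rbind, cors),
         comparison = list(
             medianUp = median(du), medianDown = median(dd),
             direction = sign(median(du) - median(dd)),
             pvalue = wt$p.value),
         evaluable = TRUE)
}

#' Hierarchical clustering and PCA diagnostics
#'
#' Selects the most variable genes, clusters samples by average-linkage
#' hierarchical clustering on correlation distance, and computes principal
#' components of the gene-centred matrix with their variance fractions.
#'
#' @param vst \linkS4class{NormalizedMatrix} or matrix of
#'   variance-stabilized values (genes x samples).
#' @param nTopVariable Number of most-variable genes (default 1000;
#'   clamped with a warning when fewer genes are available).
#' @return A list with \code{hclust} (the tree), \code{order} (sample
#'   order along the dendrogram), \code{coordinates} (samples x PCs) and
#'   \code{varianceFraction}.
#' @export
clusterAndProject <- function(vst, nTopVariable = 1000L) {
    m <- normValues(vst)
    if (ncol(m) < 3L) stop("at least 3 samples are required", call. = FALSE)
    if (nTopVariable > nrow(m)) {
        warning(sprintf("only %d genes available; using all", nrow(m)))
        nTopVariable <- nrow(m)
    }
    v <- apply(m, 1L, var)
    top <- m[order(-v)[seq_len(nTopVariable)], , drop = FALSE]
    cc <- suppressWarnings(cor(top))
    cc[is.na(cc)] <- 0
    hc <- hclust(as.dist(1 - cc), method = "average")
    centred <- top - rowMeans(top)
    pca <- prcomp(t(centred), center = FALSE)
    list(hclust = hc, order = hc$order,
         coordinates = pca$x,
         varianceFraction = pca$sdev^2 / sum(pca$sdev^2))
}
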