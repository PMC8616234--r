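# DEG-panel construction: per-subgroup versus-rest DEG union, MAD ranking,
# and a panel-size sweep scored by embedding separation.

#' Embed samples in two dimensions
#'
#' t-SNE (perplexity 20, 50000 iterations by default) or UMAP (library
#' defaults) on a features-by-samples matrix. Deterministic given
#' \code{seed}. A perplexity too large for the sample count is reduced to
#' \code{floor((n - 1) / 3)} with a warning.
#'
#' @param mat Numeric matrix, features x samples (or a
#'   \linkS4class{NormalizedMatrix}).
#' @param method \code{"tsne"} (default) or \code{"umap"}.
#' @param perplexity t-SNE perplexity (default 20).
#' @param maxIter t-SNE iterations (default 50000).
#' @param seed Integer seed.
#' @return n x 2 numeric matrix of coordinates, rownames = sample names.
#' @export
embedSamples <- function(mat, method = c("tsne", "umap"), perplexity = 20,
                         maxIter = 50000L, seed = 1L) {
    method <- match.arg(method)
    m <- normValues(mat)
    if (!all(is.finite(m)))
        stop("embedding input must be finite", call. = FALSE)
    x <- t(m)
    n <- nrow(x)
    if (n < 3L) stop("at least 3 samples are required", call. = FALSE)
    set.seed(seed)
    if (method == "tsne") {
        maxPerp <- floor((n - 1) / 3)
        if (perplexity > maxPerp) {
            warning(sprintf(
                "perplexity %g too large for %d samples; reduced to %d",
                perplexity, n, maxPerp))
            perplexity <- maxPerp
        }
        # deterministic PCA initialization: embeddings at neighbouring
        # panel sizes then differ by the data, not by the random layout
        pc <- prcomp(x, rank. = 2)$x
        init <- pc / stats::sd(pc[, 1]) * 1e-4
        coords <- Rtsne::Rtsne(x, perplexity = perplexity,
                               max_iter = maxIter, num_threads = 1,
                               check_duplicates = FALSE,
                               Y_init = init)$Y
    } else {
        coords <- uwot::umap(x, n_neighbors = min(15L, n - 1L),
                             n_threads = 1)
    }
    rownames(coords) <- rownames(x)
    colnames(coords) <- c("dim1", "dim2")
    coords
}

#' Subgroup separation score of an embedding
#'
#' Mean silhouette coefficient of the labelled samples (Euclidean distance
#' in the embedding), in [-1, 1]. Unlabelled (NA) samples are excluded;
#' at least two distinct labels are required.
#'
#' @param coords n x 2 coordinate matrix.
#' @param labels Character/factor labels, NA for unlabelled samples.
#' @return Single numeric score.
#' @export
separationScore <- function(coords, labels) {
    keep <- !is.na(labels)
    coords <- coords[keep, , drop = FALSE]
    labels <- labels[keep]
    if (length(unique(labels)) < 2L)
        stop("separation score needs at least two labels", call. = FALSE)
    sil <- cluster::silhouette(as.integer(factor(labels)), dist(coords))
    mean(sil[, "sil_width"])
}

#' Build a DEG panel by MAD sweep
#'
#' Computes the union of per-subgroup versus-rest DEGs (BH FDR below
#' \code{degFdr}; only subgroups with at least \code{minSubgroupSize}
#' labelled samples contribute a comparison, and "rest" is all other
#' samples including unlabelled ones), ranks the union by median absolute
#' deviation of the variance-stabilized values across all samples, and for
#' each candidate size scores how well the labelled subgroups separate on
#' the top genes: the mean silhouette of the labelled samples under
#' correlation distance (1 - Pearson r) in the panel expression space.
#' Scoring separation in the panel space, rather than on a 2-D embedding of
#' it, keeps the sweep deterministic and sensitive to panel completeness;
#' a stochastic 2-D projection of a well-separated cohort saturates and its
#' silhouette no longer discriminates between candidate sizes (see
#' [embedSamples()] for the visual validation step). The selected size
#' maximizes the separation score, with ties resolved toward the smallest
#' panel.
#'
#' @param counts Raw count matrix (genes x samples) used for the DE tests.
#' @param vst \linkS4class{NormalizedMatrix} (or plain matrix) of
#'   variance-stabilized values on the same genes/samples.
#' @param labels Subgroup labels per sample, NA for unknown (B-other)
#'   samples.
#' @param cfg A \linkS4class{PanelSweepConfig}.
#' @return A list with \code{panel} (character vector of panel genes at the
#'   selected size), \code{bestSize}, \code{sweep} (data.frame
#'   \code{size}, \code{score}), \code{degUnion} (the full MAD-ranked DEG
#'   union), and \code{perSubgroup} (named list of per-subgroup DEG
#'   vectors).
#' @export
buildDegPanel <- function(counts, vst, labels, cfg = panelSweepConfig()) {
    stopifnot(is(cfg, "PanelSweepConfig"))
    m <- .asCountMatrix(counts)
    v <- normValues(vst)
    if (!identical(dim(m), dim(v)))
        stop("'counts' and 'vst' must have identical shape", call. = FALSE)
    labels <- as.character(labels)
    groups <- table(labels[!is.na(labels)])
    eligible <- names(groups)[groups >= cfg@minSubgroupSize]
    if (length(eligible) < 2L)
        stop("need at least two subgroups with >= ", cfg@minSubgroupSize,
             " samples", call. = FALSE)
    factors <- sizeFactors(m)
    perSubgroup <- list()
    for (g in eligible) {
        res <- differentialExpression(m, labels == g & !is.na(labels),
                                      factors = factors)
        perSubgroup[[g]] <- res$gene[!is.na(res$padj) &
                                         res$padj < cfg@degFdr]
    }
    union <- unique(unlist(perSubgroup))
    if (!length(union))
        stop("no differentially expressed genes at FDR ", cfg@degFdr,
             call. = FALSE)
    madv <- apply(v[union, , drop = FALSE], 1L, mad)
    ranked <- union[order(-madv, union)]

    sizes <- cfg@sizes
    if (max(sizes) > length(ranked)) {
        sizes <- sizes[sizes <= length(ranked)]
        if (!length(sizes)) sizes <- length(ranked)
        warning(sprintf(
            "DEG union has %d genes; sweep grid truncated to %d size(s)",
            length(ranked), length(sizes)))
    }
    keep <- which(!is.na(labels))
    grpInt <- as.integer(factor(labels[keep]))
    scores <- vapply(sizes, function(k) {
        cc <- suppressWarnings(cor(v[ranked[seq_len(k)], keep,
                                     drop = FALSE]))
        cc[is.na(cc)] <- 0
        sil <- cluster::silhouette(grpInt, as.dist(1 - cc))
        mean(sil[, "sil_width"])
    }, numeric(1))
    best <- sizes[which(scores == max(scores))[1]]  # ties: smallest size
    list(panel = ranked[seq_len(best)], bestSize = best,
         sweep = data.frame(size = sizes, score = scores),
         degUnion = ranked, perSubgroup = perSubgroup)
}
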