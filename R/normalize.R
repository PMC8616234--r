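# GC normalization and variance stabilization of count matrices.

#' Within-lane GC-content normalization
#'
#' Per sample ("lane"), a lowess regression of log2(count + 0.5) on per-gene
#' GC fraction is fitted and the fitted GC trend removed; the sample's mean
#' log-signal is preserved exactly by adding back the mean fitted value.
#' Values are returned on the log2(count + 0.5) scale.
#'
#' @param counts Count matrix (genes x samples) or SummarizedExperiment
#'   with a \code{counts} assay and a \code{gc} rowData column.
#' @param gc Per-gene GC fraction (ignored when \code{counts} is a
#'   SummarizedExperiment carrying it). Genes with missing GC are excluded
#'   with a warning.
#' @param span lowess smoother span (default 2/3).
#' @return A \linkS4class{NormalizedMatrix} with \code{gcNormalized = TRUE}.
#' @export
gcNormalize <- function(counts, gc = NULL, span = 2 / 3) {
    if (is(counts, "SummarizedExperiment") && is.null(gc))
        gc <- SummarizedExperiment::rowData(counts)$gc
    m <- .asCountMatrix(counts)
    if (is.null(gc))
        stop("per-gene GC fractions are required", call. = FALSE)
    if (length(gc) != nrow(m))
        stop("'gc' must have one value per gene", call. = FALSE)
    if (anyNA(gc)) {
        warning(sum(is.na(gc)), " gene(s) with missing GC excluded")
        keep <- !is.na(gc)
        m <- m[keep, , drop = FALSE]
        gc <- gc[keep]
    }
    logm <- log2(m + 0.5)
    if (diff(range(gc)) == 0) {
        warning("constant GC across genes: GC normalization is a no-op")
        return(new("NormalizedMatrix", values = logm, gcNormalized = TRUE,
                   varianceStabilized = FALSE))
    }
    out <- logm
    ord <- order(gc)
    for (j in seq_len(ncol(m))) {
        fit <- lowess(gc[ord], logm[ord, j], f = span)
        fitted <- approx(fit$x, fit$y, xout = gc, rule = 2, ties = mean)$y
        out[, j] <- logm[, j] - fitted + mean(fitted)
    }
    new("NormalizedMatrix", values = out, gcNormalized = TRUE,
        varianceStabilized = FALSE)
}

#' Back-transform GC-normalized values to the count scale
#'
#' @param x A \linkS4class{NormalizedMatrix} from [gcNormalize()].
#' @return Non-negative matrix on the count scale
#'   (\code{pmax(2^values - 0.5, 0)}).
#' @export
gcCorrectedCounts <- function(x) {
    stopifnot(is(x, "NormalizedMatrix"), x@gcNormalized)
    pmax(2^x@values - 0.5, 0)
}

#' Median-of-ratios size factors
#'
#' The per-sample median of count ratios against the per-gene geometric
#' mean; genes with any zero count are excluded from the reference.
#'
#' @param counts Count matrix (genes x samples), may be non-integer (e.g.
#'   GC-corrected).
#' @return Numeric vector of size factors, one per sample.
#' @export
sizeFactors <- function(counts) {
    m <- .asCountMatrix(counts)
    allZero <- colSums(m) == 0
    if (any(allZero))
        stop("size factor undefined for all-zero sample(s): ",
             paste(colnames(m)[allZero], collapse = ", "), call. = FALSE)
    ref <- rowMeans(log(m))      # -Inf for genes with any zero
    use <- is.finite(ref)
    if (!any(use))
        stop("no gene has all-positive counts; cannot compute ",
             "median-of-ratios size factors", call. = FALSE)
    apply(m[use, , drop = FALSE], 2L,
          function(k) exp(median(log(k) - ref[use])))
}

#' Variance-stabilizing transform of counts
#'
#' Size-factor normalization (median-of-ratios) followed by the strictly
#' monotone transform \code{log2(normalized + 1)}, which makes the standard
#' deviation of NB counts approximately independent of the mean in the
#' moderately-to-highly expressed range.
#'
#' @param counts Count matrix (genes x samples) or SummarizedExperiment.
#' @param factors Optional pre-computed size factors.
#' @return A \linkS4class{NormalizedMatrix} with
#'   \code{varianceStabilized = TRUE}.
#' @examples
#' m <- matrix(rpois(200, 50), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' varianceStabilize(m)
#' @export
varianceStabilize <- function(counts, factors = NULL) {
    m <- .asCountMatrix(counts)
    if (is.null(factors)) factors <- sizeFactors(m)
    norm <- sweep(m, 2L, factors, "/")
    new("NormalizedMatrix", values = log2(norm + 1),
        gcNormalized = FALSE, varianceStabilized = TRUE)
}

#' GC-normalize then variance-stabilize a count matrix
#'
#' The standard preprocessing for embedding and panel construction:
#' within-lane GC normalization, back-transformed to the count scale, then
#' median-of-ratios variance stabilization.
#'
#' @inheritParams gcNormalize
#' @return A \linkS4class{NormalizedMatrix} with both flags set.
#' @export
normalizeExpression <- function(counts, gc = NULL, span = 2 / 3) {
    gcn <- gcNormalize(counts, gc, span)
    v <- varianceStabilize(gcCorrectedCounts(gcn))
    new("NormalizedMatrix", values = v@values, gcNormalized = TRUE,
        varianceStabilized = TRUE)
}
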