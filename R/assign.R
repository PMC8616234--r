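# Co-clustering classification of unknown samples and integration of the
# three evidence tiers (fusion > hotspot > co-clustering).

#' Assign unknown samples by co-clustering with labelled samples
#'
#' Each unknown sample's k nearest labelled neighbours under correlation
#' distance (1 - Pearson r on the panel matrix) vote; the majority label is
#' assigned when the majority fraction reaches \code{minFrac}, otherwise
#' the sample stays unassigned. Confidence is the majority fraction.
#'
#' @param panelMat Panel expression matrix (panel genes x samples), e.g.
#'   variance-stabilized values restricted to the selected panel.
#' @param labels Named character vector or per-column labels with NA for
#'   unknowns.
#' @param k Number of neighbours (default 10).
#' @param minFrac Minimum majority fraction for assignment (default 0.5).
#' @return data.frame with one row per unknown sample: \code{sample_id},
#'   \code{subtype} (NA if unassigned), \code{confidence},
#'   \code{neighbor_breakdown} (label:count pairs).
#' @export
assignByCoclustering <- function(panelMat, labels, k = 10L,
                                 minFrac = 0.5) {
    m <- normValues(panelMat)
    if (length(labels) != ncol(m))
        stop("'labels' must have one entry per sample", call. = FALSE)
    labels <- as.character(labels)
    labelled <- which(!is.na(labels))
    unknown <- which(is.na(labels))
    if (k > length(labelled))
        stop(sprintf("k = %d exceeds the %d labelled samples", k,
                     length(labelled)), call. = FALSE)
    if (!length(unknown))
        return(data.frame(sample_id = character(), subtype = character(),
                          confidence = numeric(),
                          neighbor_breakdown = character(),
                          stringsAsFactors = FALSE))
    cc <- suppressWarnings(cor(m[, unknown, drop = FALSE],
                               m[, labelled, drop = FALSE]))
    cc[is.na(cc)] <- 0
    out <- lapply(seq_along(unknown), function(i) {
        d <- 1 - cc[i, ]
        nb <- order(d)[seq_len(k)]
        votes <- sort(table(labels[labelled][nb]), decreasing = TRUE)
        top <- votes[1]
        frac <- as.numeric(top) / k
        tie <- sum(votes == as.numeric(top)) > 1L
        assigned <- frac >= minFrac && !tie
        data.frame(
            sample_id = colnames(m)[unknown[i]],
            subtype = if (assigned) names(top) else NA_character_,
            confidence = frac,
            neighbor_breakdown = paste(sprintf("%s:%d", names(votes),
                                               as.integer(votes)),
                                       collapse = ","),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Integrate fusion, hotspot and co-clustering assignments
#'
#' Final label per sample with precedence fusion > hotspot > co-clustering.
#' Tier disagreements (two tiers proposing different labels) are flagged as
#' conflicts but resolved by precedence. Samples with no evidence stay
#' unassigned.
#'
#' @param samples Character vector of all sample ids to report.
#' @param fusion data.frame from [classifyByFusion()] (or NULL).
#' @param hotspot data.frame from [classifyByHotspot()] (or NULL).
#' @param coclustering data.frame from [assignByCoclustering()] (or NULL).
#' @return data.frame with \code{sample_id}, \code{subtype},
#'   \code{evidence} (\code{fusion}, \code{hotspot}, \code{co-clustering}
#'   or \code{unassigned}), \code{confidence} (1 for fusion/hotspot tiers,
#'   the majority fraction for co-clustering, NA otherwise) and
#'   \code{conflict}.
#' @export
integrateAssignments <- function(samples, fusion = NULL, hotspot = NULL,
                                 coclustering = NULL) {
    pick <- function(df, sid) {
        if (is.null(df)) return(NA_character_)
        i <- match(sid, df$sample_id)
        if (is.na(i)) NA_character_ else df$subtype[i]
    }
    out <- lapply(samples, function(sid) {
        f <- pick(fusion, sid)
        h <- pick(hotspot, sid)
        cl <- pick(coclustering, sid)
        proposals <- stats::na.omit(c(f, h, cl))
        conflict <- length(unique(proposals)) > 1L
        if (!is.na(f)) {
            lab <- f; ev <- "fusion"; conf <- 1
        } else if (!is.na(h)) {
            lab <- h; ev <- "hotspot"; conf <- 1
        } else if (!is.na(cl)) {
            lab <- cl; ev <- "co-clustering"
            i <- match(sid, coclustering$sample_id)
            conf <- coclustering$confidence[i]
        } else {
            lab <- NA_character_; ev <- "unassigned"; conf <- NA_real_
        }
        data.frame(sample_id = sid, subtype = lab, evidence = ev,
                   confidence = conf, conflict = conflict,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Run the full B-other classification workflow
#'
#' End-to-end orchestration: filter and classify fusion calls, apply the
#' full variant cascade and classify hotspots, GC-normalize and
#' variance-stabilize the counts, build the DEG panel by MAD sweep, assign
#' unknown samples by co-clustering, and integrate the three evidence
#' tiers.
#'
#' @param counts Gene-level count matrix or SummarizedExperiment (with
#'   \code{gc} rowData when \code{gc} is not given).
#' @param gc Per-gene GC fractions.
#' @param labels Diagnostic subgroup labels per sample, NA for unknown
#'   (B-other) samples.
#' @param fusionCalls data.frame of fusion calls (may be NULL).
#' @param variants data.frame of annotated variants (may be NULL).
#' @param fusionRules A \linkS4class{FusionRuleSet}.
#' @param variantConfig A \linkS4class{VariantFilterConfig}.
#' @param hotspots Named hotspot-to-subtype map (see
#'   [classifyByHotspot()]).
#' @param sweepConfig A \linkS4class{PanelSweepConfig}.
#' @param k,minFrac Co-clustering parameters (see
#'   [assignByCoclustering()]).
#' @param embed Compute the 2-D validation embedding of all samples on the
#'   selected panel (default TRUE; uses the embedding settings of
#'   \code{sweepConfig}).
#' @return A list with \code{assignments} (integrated per-sample table over
#'   all samples), \code{panel} (the [buildDegPanel()] result),
#'   \code{embedding} (coordinates or NULL), \code{fusion}, \code{hotspot}
#'   and \code{coclustering} tier tables.
#' @export
classifyCohort <- function(counts, gc = NULL, labels, fusionCalls = NULL,
                           variants = NULL,
                           fusionRules = defaultFusionRules(),
                           variantConfig = variantFilterConfig(),
                           hotspots = c("PAX5:p.P80R" = "PAX5 P80R",
                                        "IKZF1:p.N159Y" = "IKZF1 N159Y"),
                           sweepConfig = panelSweepConfig(),
                           k = 10L, minFrac = 0.5, embed = TRUE) {
    m <- .asCountMatrix(counts)
    if (is(counts, "SummarizedExperiment") && is.null(gc))
        gc <- SummarizedExperiment::rowData(counts)$gc
    samples <- colnames(m)
    labels <- as.character(labels)

    fusionTier <- NULL
    if (!is.null(fusionCalls) && nrow(fusionCalls)) {
        retained <- filterFusions(fusionCalls, fusionRules)$retained
        if (nrow(retained)) {
            fusionTier <- classifyByFusion(retained, fusionRules)
            fusionTier <- fusionTier[!is.na(fusionTier$subtype), ,
                                     drop = FALSE]
        }
    }

    hotspotTier <- NULL
    if (!is.null(variants) && nrow(variants)) {
        kept <- applyCallerFilters(variants, variantConfig)$retained
        kept <- applyAnnotationFilters(kept, variantConfig,
                                       mode = "strict")$retained
        if (nrow(kept)) {
            hotspotTier <- classifyByHotspot(kept, hotspots)
            hotspotTier <- hotspotTier[!is.na(hotspotTier$subtype), ,
                                       drop = FALSE]
        }
    }

    vst <- normalizeExpression(m, gc)
    panel <- buildDegPanel(m, vst, labels, sweepConfig)
    coords <- NULL
    if (embed)
        coords <- suppressWarnings(embedSamples(
            normValues(vst)[panel$panel, , drop = FALSE],
            method = sweepConfig@embedding,
            perplexity = sweepConfig@tsnePerplexity,
            maxIter = sweepConfig@tsneMaxIter, seed = sweepConfig@seed))
    cocl <- assignByCoclustering(
        normValues(vst)[panel$panel, , drop = FALSE], labels,
        k = k, minFrac = minFrac)

    assignments <- integrateAssignments(samples, fusion = fusionTier,
                                        hotspot = hotspotTier,
                                        coclustering = cocl)
    # known samples keep their diagnostic label as the final call
    known <- !is.na(labels)
    assignments$subtype[known] <- labels[known]
    assignments$evidence[known] <- "diagnostic"
    assignments$confidence[known] <- 1
    list(assignments = assignments, panel = panel, embedding = coords,
         fusion = fusionTier, hotspot = hotspotTier, coclustering = cocl)
}
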