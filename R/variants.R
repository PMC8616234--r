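# Somatic-variant filter cascade on RNA-derived calls, hotspot
# classification and co-mutation summaries.

.variantRequiredCols <- c("sample_id", "chrom", "pos", "ref", "alt",
                          "alt_reads", "tumor_af")

#' Read a MAF-like annotated variant table
#'
#' Tab-separated with at least the caller-level columns
#' \code{sample_id, chrom, pos, ref, alt, alt_reads, tumor_af}; the
#' annotation-level filters additionally use \code{pop_af_max, cadd_phred,
#' variant_class, impact, polyphen, sift, condel}.
#'
#' @param path File path.
#' @return data.frame of annotated variants.
#' @export
readVariants <- function(path) {
    v <- read.delim(path, stringsAsFactors = FALSE)
    .requireColumns(v, .variantRequiredCols, "variant table")
    v
}

#' Apply caller-level variant filters
#'
#' Four rules, evaluated against the whole cohort presented together:
#' \enumerate{
#'   \item fewer than \code{minAltReads} alternative-allele reads;
#'   \item tumor allele fraction less than or equal to
#'     \code{maxTumorAFDrop};
#'   \item identical (chrom, pos, ref, alt) recurring in at least
#'     \code{maxCohortFraction} of the cohort's samples (computed on the
#'     raw input, so the cascade is order-independent);
#'   \item indels with another indel of the same sample within
#'     \code{indelWindowBp} (inclusive) on the same chromosome — both
#'     members of a close pair are removed.
#' }
#' Dropped variants carry the first violated rule in the order above.
#'
#' @param variants data.frame of variants (see [readVariants()]).
#' @param config A \linkS4class{VariantFilterConfig}.
#' @return A list with \code{retained} and \code{dropped} (with a
#'   \code{drop_reason} column: \code{low_alt_reads}, \code{low_tumor_af},
#'   \code{cohort_recurrent} or \code{indel_cluster}).
#' @examples
#' v <- data.frame(sample_id = "S1", chrom = "1", pos = c(100, 200),
#'                 ref = "A", alt = "G", alt_reads = c(5L, 20L),
#'                 tumor_af = c(0.4, 0.4))
#' applyCallerFilters(v)$dropped$drop_reason  # "low_alt_reads"
#' @export
applyCallerFilters <- function(variants, config = variantFilterConfig()) {
    stopifnot(is(config, "VariantFilterConfig"))
    .requireColumns(variants, .variantRequiredCols, "variant table")
    nSamples <- length(unique(variants$sample_id))
    if (nSamples == 1L)
        warning("single-sample cohort: the recurrence rule is computed ",
                "over one sample")
    if (!nrow(variants)) {
        d <- variants; d$drop_reason <- character(0)
        return(list(retained = variants, dropped = d))
    }

    lowAlt <- variants$alt_reads < config@minAltReads
    lowAF <- variants$tumor_af <= config@maxTumorAFDrop

    # rule 3 on the raw input: distinct samples per variant key
    key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
                 sep = ":")
    carriers <- tapply(variants$sample_id, key,
                       function(s) length(unique(s)))
    recurrent <- as.numeric(carriers[key]) / nSamples >=
        config@maxCohortFraction

    # rule 4: indel clustering within sample/chromosome
    isIndel <- nchar(variants$ref) != nchar(variants$alt)
    clustered <- rep(FALSE, nrow(variants))
    idx <- which(isIndel)
    if (length(idx) > 1L) {
        grp <- split(idx, paste(variants$sample_id[idx],
                                variants$chrom[idx]))
        for (g in grp) {
            if (length(g) < 2L) next
            pos <- variants$pos[g]
            for (a in seq_along(g)) {
                if (any(abs(pos[-a] - pos[a]) <= config@indelWindowBp))
                    clustered[g[a]] <- TRUE
            }
        }
    }

    reason <- rep(NA_character_, nrow(variants))
    reason[clustered] <- "indel_cluster"
    reason[recurrent] <- "cohort_recurrent"
    reason[lowAF] <- "low_tumor_af"
    reason[lowAlt] <- "low_alt_reads"
    keep <- is.na(reason)
    dropped <- variants[!keep, , drop = FALSE]
    dropped$drop_reason <- reason[!keep]
    list(retained = variants[keep, , drop = FALSE], dropped = dropped)
}

.annotationCols <- c("pop_af_max", "cadd_phred", "variant_class", "impact",
                     "polyphen", "sift", "condel")

#' Apply annotation-level variant filters
#'
#' In \code{strict} mode a variant is retained only if its class is not in
#' the removed set (intron, IGR, 5'flank, splice site, silent), its maximum
#' germline population allele frequency is at or below \code{maxPopAF}
#' (0.01\%), its CADD PHRED score is at least \code{minCaddPhred}, none of
#' the three predictors labels it benign (PolyPhen) / tolerated (SIFT) /
#' neutral (Condel) — missing predictor labels do not count — and its
#' impact is HIGH or MODERATE. In \code{spectrum} mode (the dataset in which
#' silent variants are retained for spectrum profiling) only the population
#' allele-frequency rule applies.
#'
#' @param variants data.frame of variants with annotation columns.
#' @param config A \linkS4class{VariantFilterConfig}.
#' @param mode \code{"strict"} or \code{"spectrum"}.
#' @return A list with \code{retained} and \code{dropped} (with
#'   \code{drop_reason}: first violated among \code{removed_class},
#'   \code{high_pop_af}, \code{low_cadd}, \code{benign_prediction},
#'   \code{low_impact}).
#' @export
applyAnnotationFilters <- function(variants,
                                   config = variantFilterConfig(),
                                   mode = c("strict", "spectrum")) {
    stopifnot(is(config, "VariantFilterConfig"))
    mode <- match.arg(mode)
    .requireColumns(variants, "pop_af_max", "variant table")
    if (mode == "strict")
        .requireColumns(variants, .annotationCols, "variant table")
    if (!nrow(variants)) {
        d <- variants; d$drop_reason <- character(0)
        return(list(retained = variants, dropped = d))
    }

    highPop <- variants$pop_af_max > config@maxPopAF
    reason <- rep(NA_character_, nrow(variants))
    if (mode == "strict") {
        lowImpact <- !variants$impact %in% config@allowedImpacts
        benign <- (!is.na(variants$polyphen) &
                       variants$polyphen == "benign") |
            (!is.na(variants$sift) & variants$sift == "tolerated") |
            (!is.na(variants$condel) & variants$condel == "neutral")
        lowCadd <- variants$cadd_phred < config@minCaddPhred
        removedClass <- variants$variant_class %in%
            config@removedClassesStrict
        reason[lowImpact] <- "low_impact"
        reason[benign] <- "benign_prediction"
        reason[lowCadd] <- "low_cadd"
        reason[highPop] <- "high_pop_af"
        reason[removedClass] <- "removed_class"
    } else {
        reason[highPop] <- "high_pop_af"
    }
    keep <- is.na(reason)
    dropped <- variants[!keep, , drop = FALSE]
    dropped$drop_reason <- reason[!keep]
    list(retained = variants[keep, , drop = FALSE], dropped = dropped)
}

#' Classify samples by hotspot mutations
#'
#' @param variants data.frame of strict-filtered variants with \code{gene}
#'   and \code{protein_change} columns.
#' @param hotspots Named character vector mapping \code{"GENE:p.Change"}
#'   keys to subtype labels, e.g.
#'   \code{c("PAX5:p.P80R" = "PAX5 P80R", "IKZF1:p.N159Y" = "IKZF1 N159Y")}.
#' @return data.frame with one row per sample in \code{variants}:
#'   \code{sample_id}, \code{subtype} (NA when no hotspot, or when multiple
#'   distinct hotspot labels conflict), \code{conflict} (logical).
#' @examples
#' v <- data.frame(sample_id = "S1", gene = "PAX5",
#'                 protein_change = "p.P80R")
#' classifyByHotspot(v)$subtype
#' @export
classifyByHotspot <- function(variants,
                              hotspots = c("PAX5:p.P80R" = "PAX5 P80R",
                                           "IKZF1:p.N159Y" = "IKZF1 N159Y")) {
    .requireColumns(variants, c("sample_id", "gene", "protein_change"),
                    "variant table")
    samples <- sort(unique(variants$sample_id))
    key <- paste(variants$gene, variants$protein_change, sep = ":")
    lab <- hotspots[key]
    out <- lapply(samples, function(sid) {
        hits <- unique(stats::na.omit(lab[variants$sample_id == sid]))
        if (length(hits) == 1L)
            data.frame(sample_id = sid, subtype = unname(hits),
                       conflict = FALSE, stringsAsFactors = FALSE)
        else
            data.frame(sample_id = sid, subtype = NA_character_,
                       conflict = length(hits) > 1L,
                       stringsAsFactors = FALSE)
    })
    if (!length(out))
        return(data.frame(sample_id = character(), subtype = character(),
                          conflict = logical(), stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Top mutated genes and gene co-mutation matrix
#'
#' A gene counts once per mutated sample. The co-occurrence entry (g1, g2)
#' is the number of samples mutated in both genes; the matrix is symmetric
#' and its diagonal holds the per-gene mutated-sample counts.
#'
#' @param variants data.frame of filtered variants with \code{sample_id}
#'   and \code{gene}.
#' @return A list with \code{topGenes} (data.frame \code{gene},
#'   \code{n_samples}, sorted decreasing, ties broken alphabetically) and
#'   \code{cooccurrence} (symmetric integer matrix).
#' @export
topMutatedAndCooccurrence <- function(variants) {
    .requireColumns(variants, c("sample_id", "gene"), "variant table")
    if (!nrow(variants))
        return(list(topGenes = data.frame(gene = character(),
                                          n_samples = integer()),
                    cooccurrence = matrix(0L, 0, 0)))
    pairs <- unique(variants[, c("sample_id", "gene")])
    genes <- sort(unique(pairs$gene))
    samples <- sort(unique(pairs$sample_id))
    ind <- matrix(0L, length(samples), length(genes),
                  dimnames = list(samples, genes))
    ind[cbind(match(pairs$sample_id, samples),
              match(pairs$gene, genes))] <- 1L
    co <- crossprod(ind)
    storage.mode(co) <- "integer"
    counts <- diag(co)
    ord <- order(-counts, genes)
    list(topGenes = data.frame(gene = genes[ord],
                               n_samples = as.integer(counts[ord]),
                               stringsAsFactors = FALSE),
         cooccurrence = co)
}
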