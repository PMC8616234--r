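#' @import methods
#' @importFrom stats median mad p.adjust pnorm pt rnbinom rpois runif rnorm
#'   rmultinom rlnorm rgamma sd var quantile cor cor.test wilcox.test lowess
#'   approx prcomp hclust as.dist dist coef glm glm.fit offset setNames
#' @importFrom utils head read.delim write.table
NULL

# ---------------------------------------------------------------------------
# SubgroupSpec ---------------------------------------------------------------

#' Specification of one BCP-ALL subgroup in a synthetic cohort
#'
#' A subgroup is defined by at least one of: a defining gene fusion (e.g.
#' \emph{ETV6-RUNX1}), a defining hotspot mutation (e.g. \emph{PAX5} p.P80R),
#' or an expression signature (a set of genes shifted by a common absolute
#' log2 fold change relative to the cohort baseline).
#'
#' @slot name Subgroup label.
#' @slot size Number of samples.
#' @slot definingFusion \code{character(2)} (5' gene, 3' gene) or empty.
#' @slot definingHotspot \code{character(2)} (gene, HGVS-p change) or empty.
#' @slot nSignatureGenes Number of signature genes (0 for none).
#' @slot signatureLog2FC Absolute log2 fold change planted on signature genes
#'   (half up, half down).
#' @slot blastFraction Leukemic blast fraction in (0, 1]; dilutes both the
#'   expression signature and fusion read support.
#' @export
setClass("SubgroupSpec",
    representation(
        name = "character",
        size = "integer",
        definingFusion = "character",
        definingHotspot = "character",
        nSignatureGenes = "integer",
        signatureLog2FC = "numeric",
        blastFraction = "numeric"
    )
)

setValidity("SubgroupSpec", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@size) != 1L || is.na(object@size) || object@size < 1L)
        msg <- c(msg, "'size' must be a positive integer")
    if (!length(object@definingFusion) %in% c(0L, 2L))
        msg <- c(msg, "'definingFusion' must be empty or a (gene5, gene3) pair")
    if (!length(object@definingHotspot) %in% c(0L, 2L))
        msg <- c(msg, "'definingHotspot' must be empty or (gene, protein_change)")
    if (object@nSignatureGenes < 0L)
        msg <- c(msg, "'nSignatureGenes' must be >= 0")
    if (length(object@definingFusion) == 0L &&
        length(object@definingHotspot) == 0L && object@nSignatureGenes == 0L)
        msg <- c(msg, "subgroup needs a fusion, a hotspot or a signature")
    if (length(object@blastFraction) != 1L || is.na(object@blastFraction) ||
        object@blastFraction <= 0 || object@blastFraction > 1)
        msg <- c(msg, "'blastFraction' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Create a subgroup specification
#'
#' @param name Subgroup label.
#' @param size Number of samples in the subgroup.
#' @param definingFusion Optional length-2 character vector (gene5, gene3).
#' @param definingHotspot Optional length-2 character vector
#'   (gene, protein change), e.g. \code{c("PAX5", "p.P80R")}.
#' @param nSignatureGenes Number of expression-signature genes.
#' @param signatureLog2FC Planted absolute log2 fold change for signature
#'   genes.
#' @param blastFraction Blast fraction in (0, 1].
#' @return A \linkS4class{SubgroupSpec}.
#' @examples
#' subgroupSpec("PAX5 P80R", size = 10,
#'              definingHotspot = c("PAX5", "p.P80R"),
#'              nSignatureGenes = 200)
#' @export
subgroupSpec <- function(name, size, definingFusion = character(),
                         definingHotspot = character(),
                         nSignatureGenes = 0L, signatureLog2FC = 2,
                         blastFraction = 0.935) {
    new("SubgroupSpec", name = name, size = as.integer(size),
        definingFusion = as.character(definingFusion),
        definingHotspot = as.character(definingHotspot),
        nSignatureGenes = as.integer(nSignatureGenes),
        signatureLog2FC = as.numeric(signatureLog2FC),
        blastFraction = as.numeric(blastFraction))
}

setMethod("show", "SubgroupSpec", function(object) {
    cat("SubgroupSpec:", object@name, "(n =", object@size, ")\n")
    if (length(object@definingFusion))
        cat("  fusion:", paste(object@definingFusion, collapse = "-"), "\n")
    if (length(object@definingHotspot))
        cat("  hotspot:", paste(object@definingHotspot, collapse = " "), "\n")
    if (object@nSignatureGenes > 0L)
        cat("  signature:", object@nSignatureGenes, "genes at |log2FC| =",
            object@signatureLog2FC, "\n")
    cat("  blast fraction:", object@blastFraction, "\n")
})

# ---------------------------------------------------------------------------
# CohortConfig ---------------------------------------------------------------

#' Configuration of a synthetic BCP-ALL cohort
#'
#' Defines everything the generator needs: subgroup structure, gene space,
#' sequencing depth, negative-binomial dispersion, GC bias, and the rates of
#' the variant classes (drivers come from the subgroup specs; passengers,
#' artifacts and A-to-I editing excess are cohort-wide rates). The seed fully
#' determines all generated outputs.
#'
#' @slot subgroups List of \linkS4class{SubgroupSpec}.
#' @slot nGenes Number of genes.
#' @slot nIsoformsPerGene Maximum isoforms per gene (isoform counts per gene
#'   are drawn uniformly from 1..max).
#' @slot librarySizeRange Length-2 numeric, sequenced read pairs per sample.
#' @slot depthScale Fraction of read pairs that land in the desk-scale count
#'   matrix (counts are drawn at librarySize * depthScale total expectation).
#' @slot nbDispersion NB dispersion alpha; variance = mu + alpha * mu^2.
#' @slot gcBiasSlope Per-sample log2-count change per unit GC fraction.
#' @slot editingExcess Expected A-to-I editing-class variants per sample.
#' @slot passengerRate Expected pathogenic-like passenger variants per sample.
#' @slot artifactRate Expected single-rule-violating artifact variants per
#'   sample (each planted artifact fails exactly one named filter rule).
#' @slot noiseFusionRate Expected false-positive fusion calls per sample.
#' @slot artifactCooccurrenceFraction Fraction of samples carrying each
#'   planted cohort-recurrent artifact variant.
#' @slot fusionReadsPerMillion Expected fusion supporting reads per million
#'   sequenced read pairs at blast fraction 1.
#' @slot seed Integer seed.
#' @export
setClass("CohortConfig",
    representation(
        subgroups = "list",
        nGenes = "integer",
        nIsoformsPerGene = "integer",
        librarySizeRange = "numeric",
        depthScale = "numeric",
        nbDispersion = "numeric",
        gcBiasSlope = "numeric",
        editingExcess = "numeric",
        passengerRate = "numeric",
        artifactRate = "numeric",
        noiseFusionRate = "numeric",
        artifactCooccurrenceFraction = "numeric",
        fusionReadsPerMillion = "numeric",
        seed = "integer"
    )
)

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (!length(object@subgroups) ||
        !all(vapply(object@subgroups, is, logical(1), "SubgroupSpec")))
        msg <- c(msg, "'subgroups' must be a non-empty list of SubgroupSpec")
    if (object@nGenes < 10L)
        msg <- c(msg, "'nGenes' must be >= 10")
    if (object@nIsoformsPerGene < 1L)
        msg <- c(msg, "'nIsoformsPerGene' must be >= 1")
    if (length(object@librarySizeRange) != 2L ||
        any(object@librarySizeRange <= 0) ||
        diff(object@librarySizeRange) < 0)
        msg <- c(msg, "'librarySizeRange' must be an increasing positive pair")
    if (object@depthScale <= 0 || object@depthScale > 1)
        msg <- c(msg, "'depthScale' must lie in (0, 1]")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "'nbDispersion' must be positive")
    for (fld in c("editingExcess", "passengerRate", "artifactRate",
                  "noiseFusionRate"))
        if (slot(object, fld) < 0)
            msg <- c(msg, sprintf("'%s' must be >= 0", fld))
    if (object@artifactCooccurrenceFraction < 0 ||
        object@artifactCooccurrenceFraction > 1)
        msg <- c(msg, "'artifactCooccurrenceFraction' must lie in [0, 1]")
    if (object@fusionReadsPerMillion <= 0)
        msg <- c(msg, "'fusionReadsPerMillion' must be positive")
    if (length(msg)) msg else TRUE
})

#' Create a cohort configuration
#'
#' @param subgroups List of \linkS4class{SubgroupSpec} objects.
#' @param nGenes Number of genes in the simulated gene space.
#' @param nIsoformsPerGene Maximum isoforms per gene.
#' @param librarySizeRange Read pairs per sample (length-2 range).
#' @param depthScale Fraction of read pairs represented in the desk-scale
#'   count matrix.
#' @param nbDispersion Negative-binomial dispersion alpha.
#' @param gcBiasSlope Sample-level GC bias slope (log2 counts per unit GC).
#' @param editingExcess Expected editing-class variants per sample.
#' @param passengerRate Expected passenger variants per sample.
#' @param artifactRate Expected artifact variants per sample.
#' @param noiseFusionRate Expected noise fusion calls per sample.
#' @param artifactCooccurrenceFraction Fraction of samples sharing each
#'   planted recurrent artifact.
#' @param fusionReadsPerMillion Expected fusion supporting reads per million
#'   read pairs at blast fraction 1.
#' @param seed Integer seed; identical configs and seeds give byte-identical
#'   outputs.
#' @return A \linkS4class{CohortConfig}.
#' @seealso [defaultCohortConfig()] for the standard five-subgroup cohort.
#' @export
cohortConfig <- function(subgroups,
                         nGenes = 2000L,
                         nIsoformsPerGene = 4L,
                         librarySizeRange = c(80e6, 130e6),
                         depthScale = 1 / 1000,
                         nbDispersion = 0.1,
                         gcBiasSlope = 1,
                         editingExcess = 30,
                         passengerRate = 5,
                         artifactRate = 2,
                         noiseFusionRate = 3,
                         artifactCooccurrenceFraction = 0.5,
                         fusionReadsPerMillion = 3,
                         seed = 1L) {
    new("CohortConfig", subgroups = subgroups, nGenes = as.integer(nGenes),
        nIsoformsPerGene = as.integer(nIsoformsPerGene),
        librarySizeRange = as.numeric(librarySizeRange),
        depthScale = as.numeric(depthScale),
        nbDispersion = as.numeric(nbDispersion),
        gcBiasSlope = as.numeric(gcBiasSlope),
        editingExcess = as.numeric(editingExcess),
        passengerRate = as.numeric(passengerRate),
        artifactRate = as.numeric(artifactRate),
        noiseFusionRate = as.numeric(noiseFusionRate),
        artifactCooccurrenceFraction = as.numeric(artifactCooccurrenceFraction),
        fusionReadsPerMillion = as.numeric(fusionReadsPerMillion),
        seed = as.integer(seed))
}

#' Number of samples in a cohort configuration
#' @param config A \linkS4class{CohortConfig}.
#' @return Integer, the sum of subgroup sizes.
#' @export
nSamples <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    sum(vapply(config@subgroups, function(s) s@size, integer(1)))
}

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig:", nSamples(object), "samples,",
        length(object@subgroups), "subgroups,", object@nGenes, "genes\n")
    for (s in object@subgroups)
        cat("  -", s@name, "(n =", s@size, ")\n")
    cat("  depth:", paste(object@librarySizeRange / 1e6, collapse = "-"),
        "M read pairs, scale", object@depthScale, "\n")
    cat("  seed:", object@seed, "\n")
})

#' Default five-subgroup synthetic cohort
#'
#' Sixty samples across five subgroups: two fusion-defined
#' (\emph{ETV6-RUNX1}, \emph{BCR-ABL1}), one hotspot-defined
#' (\emph{PAX5} p.P80R), and two defined only by expression signature
#' (\emph{DUX4}-positive-like and iAMP21-like). Each subgroup carries 200
#' signature genes at |log2FC| = 2; blast fraction defaults to 0.935, the
#' cohort-typical tumor cell content.
#'
#' @param seed Integer seed.
#' @param ... Passed on to [cohortConfig()] to override generator settings.
#' @return A \linkS4class{CohortConfig}.
#' @examples
#' cfg <- defaultCohortConfig(seed = 7)
#' nSamples(cfg)
#' @export
defaultCohortConfig <- function(seed = 1L, ...) {
    cohortConfig(
        subgroups = list(
            subgroupSpec("ETV6-RUNX1", 14,
                         definingFusion = c("ETV6", "RUNX1"),
                         nSignatureGenes = 200),
            subgroupSpec("BCR-ABL1", 14,
                         definingFusion = c("BCR", "ABL1"),
                         nSignatureGenes = 200),
            subgroupSpec("PAX5 P80R", 10,
                         definingHotspot = c("PAX5", "p.P80R"),
                         nSignatureGenes = 200),
            subgroupSpec("DUX4", 12, nSignatureGenes = 200),
            subgroupSpec("iAMP21", 10, nSignatureGenes = 200)
        ),
        seed = seed, ...)
}

# ---------------------------------------------------------------------------
# FusionRuleSet --------------------------------------------------------------

#' Fusion filtering and subtype-mapping rules
#'
#' Encodes the triage rules applied to raw fusion calls: calls with a partner
#' in the ALL-relevant gene whitelist are kept at any read support; any other
#' call is kept only if it has strictly more than
#' \code{minSupportNonWhitelist - 1} supporting reads (default: more than 10)
#' and its unordered gene pair is a known fusion (e.g. Mitelman-listed).
#' The subtype map translates retained calls into subtype labels; keys use
#' three syntaxes: \code{"A>B"} (orientation-sensitive 5'/3' pair),
#' \code{"A+B"} (unordered pair) and \code{"A"} (any fusion involving the
#' partner, e.g. any \emph{ZNF384} fusion).
#'
#' @slot whitelist Character vector of ALL-relevant gene symbols.
#' @slot knownFusions Character vector of unordered pairs \code{"A+B"}.
#' @slot minSupportNonWhitelist Minimum supporting reads for non-whitelist
#'   calls (retention requires \code{supporting >=} this; default 11,
#'   i.e. strictly more than 10).
#' @slot subtypeMap Named character vector mapping keys to subtype labels.
#' @export
setClass("FusionRuleSet",
    representation(
        whitelist = "character",
        knownFusions = "character",
        minSupportNonWhitelist = "integer",
        subtypeMap = "character"
    )
)

setValidity("FusionRuleSet", function(object) {
    msg <- character()
    if (object@minSupportNonWhitelist < 1L)
        msg <- c(msg, "'minSupportNonWhitelist' must be positive")
    if (length(object@subtypeMap) && is.null(names(object@subtypeMap)))
        msg <- c(msg, "'subtypeMap' must be named")
    if (length(msg)) msg else TRUE
})

#' Create a fusion rule set
#'
#' @param whitelist ALL-relevant gene symbols retained at any support.
#' @param knownFusions Unordered known gene pairs, as \code{"A+B"} strings or
#'   a two-column matrix/data.frame.
#' @param minSupportNonWhitelist Support threshold for non-whitelist calls
#'   (default 11: strictly more than 10 supporting reads).
#' @param subtypeMap Named character vector; see \linkS4class{FusionRuleSet}
#'   for the key syntax.
#' @return A \linkS4class{FusionRuleSet}.
#' @export
fusionRuleSet <- function(whitelist = character(),
                          knownFusions = character(),
                          minSupportNonWhitelist = 11L,
                          subtypeMap = character()) {
    if (is.matrix(knownFusions) || is.data.frame(knownFusions))
        knownFusions <- apply(as.matrix(knownFusions), 1L,
                              function(p) paste(sort(p), collapse = "+"))
    else if (length(knownFusions))
        knownFusions <- vapply(strsplit(knownFusions, "[+]"),
                               function(p) paste(sort(p), collapse = "+"),
                               character(1))
    new("FusionRuleSet", whitelist = as.character(whitelist),
        knownFusions = unique(as.character(knownFusions)),
        minSupportNonWhitelist = as.integer(minSupportNonWhitelist),
        subtypeMap = subtypeMap)
}

setMethod("show", "FusionRuleSet", function(object) {
    cat("FusionRuleSet:", length(object@whitelist), "whitelist genes,",
        length(object@knownFusions), "known fusions,",
        length(object@subtypeMap), "subtype rules\n")
    cat("  non-whitelist support threshold: >",
        object@minSupportNonWhitelist - 1L, "reads\n")
})

# ---------------------------------------------------------------------------
# VariantFilterConfig --------------------------------------------------------

#' Somatic-variant filter thresholds
#'
#' Caller-level rules (applied in \code{\link{applyCallerFilters}}): drop
#' variants with fewer than \code{minAltReads} alternative-allele reads, with
#' tumor allele fraction less than or equal to \code{maxTumorAFDrop}, with
#' identical (chrom, pos, ref, alt) recurring in at least
#' \code{maxCohortFraction} of samples, and indels within
#' \code{indelWindowBp} of another indel in the same sample.
#' Annotation-level rules (\code{\link{applyAnnotationFilters}}, strict mode):
#' remove intron/IGR/5'flank/splice-site/silent classes, population allele
#' frequency above \code{maxPopAF} in any ethnic group, CADD PHRED below
#' \code{minCaddPhred}, any predictor labelling the variant
#' benign/tolerated/neutral, and impact outside \code{allowedImpacts}.
#'
#' @slot minAltReads Integer, default 6.
#' @slot maxTumorAFDrop Real; variants with tumor AF <= this are dropped
#'   (default 0.1).
#' @slot maxCohortFraction Real, default 0.40.
#' @slot indelWindowBp Integer, default 20 (inclusive distance).
#' @slot maxPopAF Real, default 1e-4 (0.01\%).
#' @slot minCaddPhred Real, default 15.
#' @slot allowedImpacts Character, default HIGH and MODERATE.
#' @slot removedClassesStrict Character, classes removed in strict mode.
#' @export
setClass("VariantFilterConfig",
    representation(
        minAltReads = "integer",
        maxTumorAFDrop = "numeric",
        maxCohortFraction = "numeric",
        indelWindowBp = "integer",
        maxPopAF = "numeric",
        minCaddPhred = "numeric",
        allowedImpacts = "character",
        removedClassesStrict = "character"
    )
)

setValidity("VariantFilterConfig", function(object) {
    msg <- character()
    if (object@minAltReads < 0L) msg <- c(msg, "'minAltReads' must be >= 0")
    if (object@maxTumorAFDrop < 0 || object@maxTumorAFDrop > 1)
        msg <- c(msg, "'maxTumorAFDrop' must lie in [0, 1]")
    if (object@maxCohortFraction <= 0 || object@maxCohortFraction > 1)
        msg <- c(msg, "'maxCohortFraction' must lie in (0, 1]")
    if (object@indelWindowBp < 0L) msg <- c(msg, "'indelWindowBp' must be >= 0")
    if (object@maxPopAF < 0 || object@maxPopAF > 1)
        msg <- c(msg, "'maxPopAF' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Create a variant filter configuration
#'
#' Defaults implement the standard cascade; see
#' \linkS4class{VariantFilterConfig} for rule semantics.
#'
#' @param minAltReads Minimum alternative-allele reads (default 6).
#' @param maxTumorAFDrop Tumor AF at or below which a variant is dropped.
#' @param maxCohortFraction Cohort recurrence fraction triggering removal.
#' @param indelWindowBp Indel clustering window in bp (inclusive).
#' @param maxPopAF Maximum germline population AF for retention.
#' @param minCaddPhred Minimum CADD PHRED score for retention.
#' @param allowedImpacts Impact classes retained in strict mode.
#' @param removedClassesStrict Variant classes removed in strict mode.
#' @return A \linkS4class{VariantFilterConfig}.
#' @export
variantFilterConfig <- function(minAltReads = 6L,
                                maxTumorAFDrop = 0.1,
                                maxCohortFraction = 0.40,
                                indelWindowBp = 20L,
                                maxPopAF = 1e-4,
                                minCaddPhred = 15,
                                allowedImpacts = c("HIGH", "MODERATE"),
                                removedClassesStrict = c("intron", "IGR",
                                    "5'flank", "splice_site", "silent")) {
    new("VariantFilterConfig", minAltReads = as.integer(minAltReads),
        maxTumorAFDrop = as.numeric(maxTumorAFDrop),
        maxCohortFraction = as.numeric(maxCohortFraction),
        indelWindowBp = as.integer(indelWindowBp),
        maxPopAF = as.numeric(maxPopAF),
        minCaddPhred = as.numeric(minCaddPhred),
        allowedImpacts = allowedImpacts,
        removedClassesStrict = removedClassesStrict)
}

setMethod("show", "VariantFilterConfig", function(object) {
    cat("VariantFilterConfig\n")
    cat("  caller: alt reads >=", object@minAltReads,
        "| tumor AF >", object@maxTumorAFDrop,
        "| cohort recurrence <", object@maxCohortFraction,
        "| indel window", object@indelWindowBp, "bp\n")
    cat("  annotation: pop AF <=", object@maxPopAF,
        "| CADD >=", object@minCaddPhred,
        "| impact in", paste(object@allowedImpacts, collapse = "/"), "\n")
})

# ---------------------------------------------------------------------------
# PanelSweepConfig -----------------------------------------------------------

#' Configuration of the DEG-panel size sweep
#'
#' Controls panel construction: per-subgroup versus-rest differential
#' expression at \code{degFdr}, the candidate panel sizes swept (most
#' variable DEGs by MAD), and the 2-D validation embedding computed on the
#' selected panel.
#'
#' @slot sizes Increasing integer grid of candidate panel sizes
#'   (default 300 to 3000 in steps of 50; 55 sizes).
#' @slot degFdr BH FDR threshold for the per-subgroup DEG union.
#' @slot minSubgroupSize Minimum samples for a subgroup to contribute a
#'   comparison (default 3).
#' @slot embedding \code{"tsne"} or \code{"umap"} for the validation
#'   embedding.
#' @slot tsnePerplexity t-SNE perplexity (default 20).
#' @slot tsneMaxIter t-SNE iterations (default 50000).
#' @slot seed Integer seed for the embedding.
#' @export
setClass("PanelSweepConfig",
    representation(
        sizes = "integer",
        degFdr = "numeric",
        minSubgroupSize = "integer",
        embedding = "character",
        tsnePerplexity = "numeric",
        tsneMaxIter = "integer",
        seed = "integer"
    )
)

setValidity("PanelSweepConfig", function(object) {
    msg <- character()
    if (!length(object@sizes) || any(diff(object@sizes) <= 0))
        msg <- c(msg, "'sizes' must be a non-empty increasing grid")
    if (object@degFdr <= 0 || object@degFdr >= 1)
        msg <- c(msg, "'degFdr' must lie in (0, 1)")
    if (object@minSubgroupSize < 2L)
        msg <- c(msg, "'minSubgroupSize' must be >= 2")
    if (!object@embedding %in% c("tsne", "umap"))
        msg <- c(msg, "'embedding' must be 'tsne' or 'umap'")
    if (length(msg)) msg else TRUE
})

#' Create a panel sweep configuration
#'
#' @param sizes Candidate panel sizes (default \code{seq(300, 3000, 50)}).
#' @param degFdr DEG FDR threshold (default 0.05).
#' @param minSubgroupSize Minimum subgroup size for a comparison (default 3).
#' @param embedding Embedding method, \code{"tsne"} (default) or
#'   \code{"umap"}.
#' @param tsnePerplexity t-SNE perplexity (default 20).
#' @param tsneMaxIter t-SNE iterations (default 50000).
#' @param seed Integer seed.
#' @return A \linkS4class{PanelSweepConfig}.
#' @examples
#' length(panelSweepConfig()@sizes)  # 55 candidate sizes
#' @export
panelSweepConfig <- function(sizes = seq(300L, 3000L, by = 50L),
                             degFdr = 0.05, minSubgroupSize = 3L,
                             embedding = c("tsne", "umap"),
                             tsnePerplexity = 20, tsneMaxIter = 50000L,
                             seed = 1L) {
    new("PanelSweepConfig", sizes = as.integer(sizes),
        degFdr = as.numeric(degFdr),
        minSubgroupSize = as.integer(minSubgroupSize),
        embedding = match.arg(embedding),
        tsnePerplexity = as.numeric(tsnePerplexity),
        tsneMaxIter = as.integer(tsneMaxIter), seed = as.integer(seed))
}

setMethod("show", "PanelSweepConfig", function(object) {
    cat("PanelSweepConfig:", length(object@sizes), "candidate sizes (",
        min(object@sizes), "-", max(object@sizes), "),",
        object@embedding, "embedding\n")
})

# ---------------------------------------------------------------------------
# NormalizedMatrix -----------------------------------------------------------

#' Normalized expression matrix with provenance flags
#'
#' Carries a genes-by-samples real matrix together with flags recording which
#' normalizations produced it. Values are on log2 scale after either
#' operation.
#'
#' @slot values Numeric matrix (features x samples).
#' @slot gcNormalized Logical flag.
#' @slot varianceStabilized Logical flag.
#' @export
setClass("NormalizedMatrix",
    representation(
        values = "matrix",
        gcNormalized = "logical",
        varianceStabilized = "logical"
    )
)

setValidity("NormalizedMatrix", function(object) {
    if (!all(is.finite(object@values)))
        "all entries must be finite" else TRUE
})

#' Extract the numeric values of a NormalizedMatrix
#' @param x A \linkS4class{NormalizedMatrix} (a plain matrix passes through).
#' @return Numeric matrix, features x samples.
#' @export
normValues <- function(x) {
    if (is(x, "NormalizedMatrix")) x@values else as.matrix(x)
}

setMethod("show", "NormalizedMatrix", function(object) {
    cat("NormalizedMatrix:", nrow(object@values), "features x",
        ncol(object@values), "samples",
        if (object@gcNormalized) "| GC-normalized" else "",
        if (object@varianceStabilized) "| variance-stabilized" else "", "\n")
})

setMethod("dim", "NormalizedMatrix", function(x) dim(x@values))
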