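# Synthetic cohort generator: expression, fusion calls, variants, paired
# tubes, isoform counts. Everything is deterministic given the config seed;
# each generator uses its own seed offset so the outputs of one do not
# depend on whether another was run.

# shared per-sample frame: ids, subgroup, blast fraction, library size.
# Drawn at the config seed itself so every generator sees the same samples.
.sampleFrame <- function(config) {
    set.seed(config@seed)
    subgroup <- unlist(lapply(config@subgroups,
                              function(s) rep(s@name, s@size)))
    n <- length(subgroup)
    blast <- unlist(lapply(config@subgroups,
                           function(s) rep(s@blastFraction, s@size)))
    lib <- runif(n, config@librarySizeRange[1], config@librarySizeRange[2])
    data.frame(
        sample_id = sprintf("S%03d", seq_len(n)),
        subgroup = subgroup,
        blast_fraction = blast,
        library_size = lib,
        stringsAsFactors = FALSE
    )
}

# gene space: ids, GC fraction, length, baseline relative expression weight,
# and disjoint signature-gene blocks per subgroup. Signature genes are drawn
# from the moderately-to-highly expressed stratum (subtype signatures are
# detectable genes, not the noise floor).
.geneFrame <- function(config) {
    set.seed(config@seed)
    ng <- config@nGenes
    genes <- data.frame(
        gene = sprintf("G%05d", seq_len(ng)),
        gc = round(runif(ng, 0.30, 0.70), 4),
        length = round(rlnorm(ng, log(1500), 0.5)),
        weight = rlnorm(ng, meanlog = 3, sdlog = 1.3),
        stringsAsFactors = FALSE
    )
    eligible <- which(genes$weight >= quantile(genes$weight, 0.40))
    eligible <- sample(eligible)
    sig <- vector("list", length(config@subgroups))
    names(sig) <- vapply(config@subgroups, function(s) s@name, character(1))
    used <- 0L
    for (i in seq_along(config@subgroups)) {
        k <- config@subgroups[[i]]@nSignatureGenes
        if (k > 0L) {
            if (used + k > length(eligible))
                stop("not enough genes for the requested signature sizes")
            idx <- eligible[(used + 1L):(used + k)]
            used <- used + k
            sig[[i]] <- data.frame(
                gene = genes$gene[idx],
                direction = rep_len(c(1, -1), k),
                stringsAsFactors = FALSE
            )
        } else {
            sig[[i]] <- data.frame(gene = character(),
                                   direction = numeric())
        }
    }
    list(genes = genes, signature = sig)
}

#' Simulate a gene-level count matrix for a synthetic cohort
#'
#' Counts are negative-binomial (variance = mu + alpha mu^2) around
#' per-sample expected values built from a cohort-wide baseline expression
#' profile. For each subgroup, signature genes are shifted by the subgroup's
#' log2 fold change in the leukemic profile; the observed profile is the
#' blast-fraction mixture \code{bf * leukemic + (1 - bf) * baseline}, so low
#' blast fractions attenuate the signature toward the shared baseline. A
#' per-sample GC bias (random slope around the configured value) multiplies
#' expected counts by \code{2^(slope * (gc - mean(gc)))}.
#'
#' @param config A \linkS4class{CohortConfig}.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{counts}, rowData columns \code{gc}, \code{length}, colData
#'   columns \code{subgroup}, \code{blast_fraction}, \code{library_size},
#'   and ground truth in \code{metadata()$groundTruth} (per-subgroup
#'   signature gene tables with planted directions; genes are only labelled
#'   as planted-DE when the subgroup's log2 fold change is non-zero).
#' @examples
#' se <- simulateExpression(defaultCohortConfig(seed = 1))
#' dim(se)
#' @export
simulateExpression <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    samples <- .sampleFrame(config)
    gf <- .geneFrame(config)
    genes <- gf$genes
    n <- nrow(samples)
    ng <- nrow(genes)

    set.seed(config@seed + 101L)
    gcCentered <- genes$gc - mean(genes$gc)
    slope <- if (config@gcBiasSlope == 0) rep(0, n) else
        config@gcBiasSlope * runif(n, 0.5, 1.5)

    specByName <- stats::setNames(config@subgroups,
        vapply(config@subgroups, function(s) s@name, character(1)))
    counts <- matrix(0L, ng, n,
                     dimnames = list(genes$gene, samples$sample_id))
    expectedMean <- matrix(0, ng, n,
                           dimnames = dimnames(counts))
    depth <- samples$library_size * config@depthScale
    for (j in seq_len(n)) {
        sg <- samples$subgroup[j]
        spec <- specByName[[sg]]
        wLeuk <- genes$weight
        sigTab <- gf$signature[[sg]]
        if (nrow(sigTab) && spec@signatureLog2FC != 0) {
            idx <- match(sigTab$gene, genes$gene)
            wLeuk[idx] <- wLeuk[idx] *
                2^(sigTab$direction * spec@signatureLog2FC)
        }
        bf <- samples$blast_fraction[j]
        w <- bf * wLeuk + (1 - bf) * genes$weight
        w <- w * 2^(slope[j] * gcCentered)
        mu <- depth[j] * w / sum(w)
        expectedMean[, j] <- mu
        counts[, j] <- rnbinom(ng, mu = mu, size = 1 / config@nbDispersion)
    }

    truthSig <- lapply(seq_along(config@subgroups), function(i) {
        if (config@subgroups[[i]]@signatureLog2FC == 0)
            data.frame(gene = character(), direction = numeric())
        else gf$signature[[i]]
    })
    names(truthSig) <- names(gf$signature)

    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gc = genes$gc,
                                       length = genes$length,
                                       row.names = genes$gene),
        colData = S4Vectors::DataFrame(
            subgroup = samples$subgroup,
            blast_fraction = samples$blast_fraction,
            library_size = samples$library_size,
            row.names = samples$sample_id),
        metadata = list(groundTruth = list(
            subtype = stats::setNames(samples$subgroup, samples$sample_id),
            signature = truthSig,
            expectedMean = expectedMean))
    )
}

# pool of plausible but irrelevant gene symbols used for noise fusions and
# passenger/artifact variants; disjoint from the default whitelist
.noiseGenePool <- function(n = 400L) sprintf("GN%04d", seq_len(n))

.randomChrom <- function(n) sample(c(as.character(1:22), "X"), n,
                                   replace = TRUE)

#' Simulate fusion calls for a synthetic cohort
#'
#' For each subgroup with a defining fusion, every sample of the subgroup
#' emits a call for that fusion with total supporting reads drawn Poisson
#' with expectation \code{fusionReadsPerMillion * librarySize/1e6 *
#' blastFraction} (split/spanning reads split binomially); a call is emitted
#' only if at least one supporting read is drawn. Noise calls (random
#' non-whitelist gene pairs with low support) are added per sample at rate
#' \code{noiseFusionRate}.
#'
#' @param config A \linkS4class{CohortConfig}.
#' @return A list with \code{calls} (data.frame with columns
#'   \code{sample_id, gene5, gene3, breakpoint5, breakpoint3, split_reads,
#'   spanning_reads}) and \code{truth} (data.frame with the same keys plus
#'   \code{class} = \code{"true"} or \code{"noise"}; planted fusions that
#'   drew zero reads are listed with class \code{"dropout"}).
#' @examples
#' fc <- simulateFusionCalls(defaultCohortConfig(seed = 1))
#' head(fc$calls)
#' @export
simulateFusionCalls <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    samples <- .sampleFrame(config)
    set.seed(config@seed + 202L)

    specByName <- stats::setNames(config@subgroups,
        vapply(config@subgroups, function(s) s@name, character(1)))
    pool <- .noiseGenePool()
    rows <- list()
    truth <- list()
    for (j in seq_len(nrow(samples))) {
        sid <- samples$sample_id[j]
        spec <- specByName[[samples$subgroup[j]]]
        if (length(spec@definingFusion) == 2L) {
            lambda <- config@fusionReadsPerMillion *
                (samples$library_size[j] / 1e6) * samples$blast_fraction[j]
            total <- rpois(1, lambda)
            if (total >= 1L) {
                split <- stats::rbinom(1, total, 0.6)
                rows[[length(rows) + 1L]] <- data.frame(
                    sample_id = sid,
                    gene5 = spec@definingFusion[1],
                    gene3 = spec@definingFusion[2],
                    breakpoint5 = sprintf("%s:%d", .randomChrom(1),
                                          sample.int(2e8, 1)),
                    breakpoint3 = sprintf("%s:%d", .randomChrom(1),
                                          sample.int(2e8, 1)),
                    split_reads = split,
                    spanning_reads = total - split,
                    stringsAsFactors = FALSE)
                truth[[length(truth) + 1L]] <- data.frame(
                    sample_id = sid, gene5 = spec@definingFusion[1],
                    gene3 = spec@definingFusion[2], class = "true",
                    stringsAsFactors = FALSE)
            } else {
                truth[[length(truth) + 1L]] <- data.frame(
                    sample_id = sid, gene5 = spec@definingFusion[1],
                    gene3 = spec@definingFusion[2], class = "dropout",
                    stringsAsFactors = FALSE)
            }
        }
        nNoise <- rpois(1, config@noiseFusionRate)
        if (nNoise > 0L) {
            for (k in seq_len(nNoise)) {
                gp <- sample(pool, 2L)
                split <- rpois(1, 1.5) + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    sample_id = sid, gene5 = gp[1], gene3 = gp[2],
                    breakpoint5 = sprintf("%s:%d", .randomChrom(1),
                                          sample.int(2e8, 1)),
                    breakpoint3 = sprintf("%s:%d", .randomChrom(1),
                                          sample.int(2e8, 1)),
                    split_reads = split,
                    spanning_reads = rpois(1, 1),
                    stringsAsFactors = FALSE)
                truth[[length(truth) + 1L]] <- data.frame(
                    sample_id = sid, gene5 = gp[1], gene3 = gp[2],
                    class = "noise", stringsAsFactors = FALSE)
            }
        }
    }
    emptyCalls <- data.frame(sample_id = character(), gene5 = character(),
                             gene3 = character(), breakpoint5 = character(),
                             breakpoint3 = character(),
                             split_reads = integer(),
                             spanning_reads = integer(),
                             stringsAsFactors = FALSE)
    emptyTruth <- data.frame(sample_id = character(), gene5 = character(),
                             gene3 = character(), class = character(),
                             stringsAsFactors = FALSE)
    list(calls = if (length(rows)) do.call(rbind, rows) else emptyCalls,
         truth = if (length(truth)) do.call(rbind, truth) else emptyTruth)
}

# annotation presets used by the variant generator
.passingAnnotation <- function(n) {
    data.frame(
        pop_af_max = rep(0, n), cadd_phred = runif(n, 22, 35),
        consequence = rep("missense_variant", n),
        variant_class = rep("missense", n), impact = rep("MODERATE", n),
        polyphen = rep("probably_damaging", n),
        sift = rep("deleterious", n), condel = rep("deleterious", n),
        stringsAsFactors = FALSE
    )
}

.substitutionPair <- function(n) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

.variantRow <- function(sample_id, gene, chrom, pos, ref, alt, alt_reads,
                        tumor_af, ann, protein_change = NA_character_) {
    data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
               alt = alt, alt_reads = alt_reads, tumor_af = tumor_af,
               pop_af_max = ann$pop_af_max, cadd_phred = ann$cadd_phred,
               consequence = ann$consequence,
               variant_class = ann$variant_class, impact = ann$impact,
               polyphen = ann$polyphen, sift = ann$sift,
               condel = ann$condel, gene = gene,
               protein_change = protein_change,
               is_indel = nchar(ref) != nchar(alt),
               stringsAsFactors = FALSE)
}

#' Simulate annotated somatic variant calls for a synthetic cohort
#'
#' Emits four ground-truth classes: \emph{drivers} (the defining hotspot of
#' each hotspot subgroup, annotated to pass the full strict cascade),
#' \emph{passengers} (pathogenic-like, also cascade-passing, at
#' \code{passengerRate} per sample), \emph{artifacts} (each violating exactly
#' one named filter rule, at \code{artifactRate} per sample, plus planted
#' cohort-recurrent artifacts shared by \code{artifactCooccurrenceFraction}
#' of samples), and \emph{editing} (A-to-I excess: T>C or A>G substitutions
#' with tumor AF in [0.1, 0.6] so they survive caller-level filters but are
#' largely removed by the strict annotation filters, at
#' \code{editingExcess} per sample).
#'
#' @param config A \linkS4class{CohortConfig}.
#' @return A list with \code{variants} (data.frame, one row per call, with
#'   a \code{variant_id} key) and \code{truth} (data.frame with
#'   \code{variant_id}, \code{class} in driver/passenger/artifact/editing,
#'   and \code{violated_rule}, the single named rule each artifact breaks,
#'   NA for other classes).
#' @examples
#' v <- simulateVariants(defaultCohortConfig(seed = 1))
#' table(v$truth$class)
#' @export
simulateVariants <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    samples <- .sampleFrame(config)
    set.seed(config@seed + 303L)
    n <- nrow(samples)
    specByName <- stats::setNames(config@subgroups,
        vapply(config@subgroups, function(s) s@name, character(1)))
    pool <- .noiseGenePool()
    rows <- list()
    classes <- character()
    ruleViol <- character()

    addRow <- function(row, class, rule = NA_character_) {
        rows[[length(rows) + 1L]] <<- row
        classes[length(classes) + 1L] <<- class
        ruleViol[length(ruleViol) + 1L] <<- rule
    }

    # stable hotspot coordinates per (gene, change)
    hotspotPos <- new.env(parent = emptyenv())
    hsCoord <- function(gene, change) {
        key <- paste(gene, change)
        if (is.null(hotspotPos[[key]]))
            hotspotPos[[key]] <- list(chrom = .randomChrom(1),
                                      pos = sample.int(2e8, 1))
        hotspotPos[[key]]
    }

    artifactKinds <- c("low_alt_reads", "low_tumor_af", "indel_cluster",
                       "high_pop_af", "low_cadd", "benign_prediction",
                       "removed_class", "low_impact")

    for (j in seq_len(n)) {
        sid <- samples$sample_id[j]
        spec <- specByName[[samples$subgroup[j]]]

        # driver hotspot
        if (length(spec@definingHotspot) == 2L) {
            co <- hsCoord(spec@definingHotspot[1], spec@definingHotspot[2])
            sub <- .substitutionPair(1)
            addRow(.variantRow(sid, spec@definingHotspot[1], co$chrom,
                               co$pos, sub$ref, sub$alt,
                               alt_reads = 20L + rpois(1, 20),
                               tumor_af = round(runif(1, 0.3, 0.55), 3),
                               ann = .passingAnnotation(1),
                               protein_change = spec@definingHotspot[2]),
                   "driver")
        }

        # passengers: pass every rule
        nPass <- rpois(1, config@passengerRate)
        for (k in seq_len(nPass)) {
            sub <- .substitutionPair(1)
            addRow(.variantRow(sid, sample(pool, 1), .randomChrom(1),
                               sample.int(2e8, 1), sub$ref, sub$alt,
                               alt_reads = 6L + rpois(1, 30),
                               tumor_af = round(runif(1, 0.15, 0.6), 3),
                               ann = .passingAnnotation(1),
                               protein_change = sprintf("p.X%dY",
                                   sample.int(900, 1))),
                   "passenger")
        }

        # artifacts: each violates exactly one named rule
        nArt <- rpois(1, config@artifactRate)
        for (k in seq_len(nArt)) {
            kind <- sample(artifactKinds, 1)
            ann <- .passingAnnotation(1)
            sub <- .substitutionPair(1)
            alt_reads <- 6L + rpois(1, 30)
            tumor_af <- round(runif(1, 0.15, 0.6), 3)
            chrom <- .randomChrom(1)
            pos <- sample.int(2e8, 1)
            ref <- sub$ref; alt <- sub$alt
            if (kind == "low_alt_reads") {
                alt_reads <- sample.int(5L, 1)
            } else if (kind == "low_tumor_af") {
                tumor_af <- round(runif(1, 0.01, 0.1), 3)
            } else if (kind == "high_pop_af") {
                ann$pop_af_max <- round(runif(1, 2e-4, 5e-2), 6)
            } else if (kind == "low_cadd") {
                ann$cadd_phred <- round(runif(1, 0, 14.9), 2)
            } else if (kind == "benign_prediction") {
                which <- sample(3L, 1)
                if (which == 1L) ann$polyphen <- "benign"
                else if (which == 2L) ann$sift <- "tolerated"
                else ann$condel <- "neutral"
            } else if (kind == "removed_class") {
                cls <- sample(c("intron", "IGR", "5'flank", "splice_site",
                                "silent"), 1)
                ann$variant_class <- cls
                ann$consequence <- switch(cls,
                    intron = "intron_variant", IGR = "intergenic_variant",
                    "5'flank" = "upstream_gene_variant",
                    splice_site = "splice_region_variant",
                    silent = "synonymous_variant")
                # impact kept MODERATE so only the class rule fires
            } else if (kind == "low_impact") {
                ann$impact <- sample(c("LOW", "MODIFIER"), 1)
            }
            if (kind == "indel_cluster") {
                # a pair of nearby indels; both violate only the window rule
                for (off in c(0L, sample.int(20L, 1))) {
                    addRow(.variantRow(sid, sample(pool, 1), chrom,
                                       pos + off, "A", "AT",
                                       alt_reads = 6L + rpois(1, 30),
                                       tumor_af = round(runif(1, 0.15, 0.6),
                                                        3),
                                       ann = .passingAnnotation(1)),
                           "artifact", kind)
                }
            } else {
                addRow(.variantRow(sid, sample(pool, 1), chrom, pos, ref,
                                   alt, alt_reads, tumor_af, ann),
                       "artifact", kind)
            }
        }

        # A-to-I editing excess: T>C / A>G, AF in [0.1, 0.6]
        nEd <- rpois(1, config@editingExcess)
        if (nEd > 0L) {
            strandT <- stats::rbinom(nEd, 1, 0.5) == 1L
            for (k in seq_len(nEd)) {
                ann <- data.frame(
                    pop_af_max = 0,
                    cadd_phred = round(runif(1, 0, 12), 2),
                    consequence = sample(c("missense_variant",
                                           "synonymous_variant"), 1),
                    variant_class = NA_character_,
                    impact = sample(c("LOW", "MODIFIER", "MODERATE"), 1,
                                    prob = c(0.4, 0.4, 0.2)),
                    polyphen = "benign", sift = "tolerated",
                    condel = "neutral", stringsAsFactors = FALSE)
                ann$variant_class <- if (ann$consequence ==
                    "synonymous_variant") "silent" else "missense"
                addRow(.variantRow(sid, sample(pool, 1), .randomChrom(1),
                                   sample.int(2e8, 1),
                                   ref = if (strandT[k]) "T" else "A",
                                   alt = if (strandT[k]) "C" else "G",
                                   alt_reads = 6L + rpois(1, 15),
                                   tumor_af = round(runif(1, 0.1, 0.6), 3),
                                   ann = ann),
                       "editing")
            }
        }
    }

    # cohort-recurrent artifacts: identical (chrom,pos,ref,alt) planted in
    # at least artifactCooccurrenceFraction of samples
    if (config@artifactCooccurrenceFraction > 0 && n >= 2L &&
        config@artifactRate > 0) {
        nCarriers <- max(2L, ceiling(config@artifactCooccurrenceFraction * n))
        for (r in 1:2) {
            chrom <- .randomChrom(1); pos <- sample.int(2e8, 1)
            sub <- .substitutionPair(1)
            carriers <- sample(samples$sample_id, nCarriers)
            for (sid in carriers)
                addRow(.variantRow(sid, sample(pool, 1), chrom, pos,
                                   sub$ref, sub$alt,
                                   alt_reads = 6L + rpois(1, 30),
                                   tumor_af = round(runif(1, 0.15, 0.6), 3),
                                   ann = .passingAnnotation(1)),
                       "artifact", "cohort_recurrent")
        }
    }

    if (!length(rows)) {
        variants <- .variantRow(character(), character(), character(),
                                integer(), character(), character(),
                                integer(), numeric(),
                                .passingAnnotation(0))[0, ]
        variants$variant_id <- character()
        return(list(variants = variants,
                    truth = data.frame(variant_id = character(),
                                       class = character(),
                                       violated_rule = character(),
                                       stringsAsFactors = FALSE)))
    }
    variants <- do.call(rbind, rows)
    variants$variant_id <- sprintf("V%06d", seq_len(nrow(variants)))
    list(variants = variants,
         truth = data.frame(variant_id = variants$variant_id,
                            class = classes, violated_rule = ruleViol,
                            stringsAsFactors = FALSE))
}

#' Simulate patient-paired collection-tube samples
#'
#' Two samples per patient (PAXgene and EDTA conditions) share a
#' patient-specific log-normal baseline per gene (log2 sd =
#' \code{patientSD}); a tube effect of \code{tubeLog2FC} (half up, half
#' down) is added to the first \code{nTubeEffectGenes} genes in the PAXgene
#' condition only.
#'
#' @param nPatients Number of patients (>= 2).
#' @param nGenes Number of genes.
#' @param nTubeEffectGenes Number of genes carrying the planted tube effect.
#' @param tubeLog2FC Absolute log2 fold change of the tube effect; 0 plants
#'   no effect (the truth gene set is then empty).
#' @param patientSD Log2 sd of the patient-specific per-gene baseline.
#' @param nbDispersion NB dispersion alpha.
#' @param seed Integer seed.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{counts}, colData \code{patient}, \code{condition}, and ground
#'   truth (\code{tubeEffectGenes} with directions) in
#'   \code{metadata()$groundTruth}.
#' @examples
#' se <- simulatePairedTubes(nPatients = 6, nGenes = 500, seed = 1)
#' table(SummarizedExperiment::colData(se)$condition)
#' @export
simulatePairedTubes <- function(nPatients = 6L, nGenes = 2000L,
                                nTubeEffectGenes = 100L, tubeLog2FC = 3,
                                patientSD = 1, nbDispersion = 0.05,
                                seed = 1L) {
    if (nPatients < 2L)
        stop("'nPatients' must be >= 2", call. = FALSE)
    if (nTubeEffectGenes > nGenes)
        stop("'nTubeEffectGenes' cannot exceed 'nGenes'", call. = FALSE)
    set.seed(seed)
    geneIds <- sprintf("G%05d", seq_len(nGenes))
    baseMu <- rlnorm(nGenes, log(80), 1.2)
    effGenes <- if (tubeLog2FC == 0) integer(0) else seq_len(nTubeEffectGenes)
    dirs <- rep_len(c(1, -1), length(effGenes))

    n <- 2L * nPatients
    patient <- rep(sprintf("P%02d", seq_len(nPatients)), each = 2L)
    condition <- rep(c("PAXgene", "EDTA"), nPatients)
    counts <- matrix(0L, nGenes, n)
    sampleIds <- paste(patient, condition, sep = "_")
    dimnames(counts) <- list(geneIds, sampleIds)
    for (p in seq_len(nPatients)) {
        patEff <- rnorm(nGenes, 0, patientSD)   # log2 scale
        for (cidx in 1:2) {
            j <- 2L * (p - 1L) + cidx
            lf <- rep(0, nGenes)
            if (condition[j] == "PAXgene" && length(effGenes))
                lf[effGenes] <- dirs * tubeLog2FC
            depthFactor <- 2^rnorm(1, 0, 0.15)
            mu <- baseMu * 2^(patEff + lf) * depthFactor
            counts[, j] <- rnbinom(nGenes, mu = mu,
                                   size = 1 / nbDispersion)
        }
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(patient = patient,
                                       condition = condition,
                                       row.names = sampleIds),
        metadata = list(groundTruth = list(
            tubeEffectGenes = data.frame(
                gene = geneIds[effGenes],
                direction = dirs,
                log2fc = rep(tubeLog2FC, length(effGenes)),
                stringsAsFactors = FALSE)))
    )
}

#' Simulate isoform-level counts nested within gene-level counts
#'
#' For each gene, the number of isoforms is drawn uniformly from
#' 1..\code{maxIsoforms} and per-sample isoform counts are multinomial
#' within the gene's observed total, so isoform counts always sum exactly to
#' the gene count. Usage shifts replace the baseline isoform proportions in
#' designated samples.
#'
#' @param geneCounts Gene-level count matrix (genes x samples) or a
#'   SummarizedExperiment with a \code{counts} assay.
#' @param usageShifts Optional list of shift specs, each a list with
#'   \code{gene}, \code{samples} (character vector of sample ids) and
#'   \code{proportions} (numeric, one per isoform of the gene, summing
#'   to 1).
#' @param maxIsoforms Maximum isoforms per gene (default 4).
#' @param seed Integer seed.
#' @return A list with \code{counts} (isoform x sample integer matrix),
#'   \code{map} (data.frame \code{isoform_id}, \code{gene_id}) and
#'   \code{truth} (data.frame of applied shifts, one row per shifted
#'   isoform/sample-group with baseline and shifted proportion).
#' @examples
#' gc <- matrix(rpois(50, 100), 5, 10,
#'              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
#' iso <- simulateIsoformCounts(gc, seed = 1)
#' all(rowsum(iso$counts, iso$map$gene_id) == gc[sort(rownames(gc)), ])
#' @export
simulateIsoformCounts <- function(geneCounts, usageShifts = list(),
                                  maxIsoforms = 4L, seed = 1L) {
    counts <- .asCountMatrix(geneCounts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'geneCounts' must have row (gene) and column (sample) names",
             call. = FALSE)
    set.seed(seed)
    genes <- rownames(counts)
    nIso <- sample.int(maxIsoforms, length(genes), replace = TRUE)
    names(nIso) <- genes
    baseProps <- lapply(nIso, function(k) {
        p <- rgamma(k, shape = 2)
        p / sum(p)
    })

    for (sh in usageShifts) {
        if (!all(c("gene", "samples", "proportions") %in% names(sh)))
            stop("each usage shift needs 'gene', 'samples', 'proportions'",
                 call. = FALSE)
        if (!sh$gene %in% genes)
            stop(sprintf("usage shift references unknown gene '%s'",
                         sh$gene), call. = FALSE)
        if (nIso[[sh$gene]] < 2L)
            stop(sprintf(
                "usage shift on single-isoform gene '%s' is not allowed",
                sh$gene), call. = FALSE)
        if (length(sh$proportions) != nIso[[sh$gene]])
            stop(sprintf("shift proportions for '%s' must have length %d",
                         sh$gene, nIso[[sh$gene]]), call. = FALSE)
    }

    isoIds <- unlist(lapply(genes, function(g)
        sprintf("%s.i%d", g, seq_len(nIso[[g]]))), use.names = FALSE)
    map <- data.frame(
        isoform_id = isoIds,
        gene_id = rep(genes, nIso),
        stringsAsFactors = FALSE)

    shiftByGene <- list()
    for (sh in usageShifts)
        shiftByGene[[sh$gene]] <- c(shiftByGene[[sh$gene]], list(sh))

    iso <- matrix(0L, length(isoIds), ncol(counts),
                  dimnames = list(isoIds, colnames(counts)))
    offset <- 0L
    truthRows <- list()
    for (gi in seq_along(genes)) {
        g <- genes[gi]
        k <- nIso[[g]]
        idx <- offset + seq_len(k)
        offset <- offset + k
        propBySample <- matrix(baseProps[[g]], k, ncol(counts))
        for (sh in shiftByGene[[g]]) {
            jj <- match(sh$samples, colnames(counts))
            if (anyNA(jj))
                stop("usage shift references unknown sample(s)",
                     call. = FALSE)
            propBySample[, jj] <- sh$proportions
            truthRows[[length(truthRows) + 1L]] <- data.frame(
                gene_id = g,
                isoform_id = sprintf("%s.i%d", g, seq_len(k)),
                baseline_proportion = baseProps[[g]],
                shifted_proportion = sh$proportions,
                samples = paste(sh$samples, collapse = ","),
                stringsAsFactors = FALSE)
        }
        for (j in seq_len(ncol(counts))) {
            tot <- counts[gi, j]
            if (tot > 0)
                iso[idx, j] <- rmultinom(1, tot, propBySample[, j])[, 1]
        }
    }
    truth <- if (length(truthRows)) do.call(rbind, truthRows) else
        data.frame(gene_id = character(), isoform_id = character(),
                   baseline_proportion = numeric(),
                   shifted_proportion = numeric(), samples = character(),
                   stringsAsFactors = FALSE)
    list(counts = iso, map = map, truth = truth)
}
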