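# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
    if (is.null(.fixtureCache[[name]]))
        .fixtureCache[[name]] <- builder()
    .fixtureCache[[name]]
}

# the default five-subgroup cohort with a fixed seed, plus a held-out
# labelling (a third of each subgroup masked as unknown)
defaultCohortFixture <- function() {
    cached("defaultCohort", function() {
        cfg <- defaultCohortConfig(seed = 11)
        se <- simulateExpression(cfg)
        truth <- S4Vectors::metadata(se)$groundTruth$subtype
        set.seed(1111)
        unknownIdx <- unlist(lapply(split(seq_along(truth), truth),
                                    function(i)
                                        sample(i, ceiling(length(i) / 3))))
        labels <- truth
        labels[unknownIdx] <- NA
        list(config = cfg, se = se, truth = truth, labels = labels,
             unknownIdx = unknownIdx,
             fusions = simulateFusionCalls(cfg),
             variants = simulateVariants(cfg))
    })
}

# vst + panel on the default cohort (reused by panel/assignment tests)
defaultPanelFixture <- function() {
    cached("defaultPanel", function() {
        fx <- defaultCohortFixture()
        m <- SummarizedExperiment::assay(fx$se)
        vst <- normalizeExpression(fx$se)
        panel <- suppressWarnings(
            buildDegPanel(m, vst, fx$labels, panelSweepConfig()))
        list(m = m, vst = vst, panel = panel)
    })
}

# brute-force re-implementations used as independent oracles -----------------

bruteForceFusionFilter <- function(calls, rules) {
    keep <- logical(nrow(calls))
    for (i in seq_len(nrow(calls))) {
        supp <- calls$split_reads[i] + calls$spanning_reads[i]
        wl <- calls$gene5[i] %in% rules@whitelist ||
            calls$gene3[i] %in% rules@whitelist
        pair <- paste(sort(c(calls$gene5[i], calls$gene3[i])),
                      collapse = "+")
        keep[i] <- wl || (supp > 10 && pair %in% rules@knownFusions)
    }
    keep
}

bruteForceCallerFilter <- function(variants, cfg = variantFilterConfig()) {
    n <- nrow(variants)
    nSamp <- length(unique(variants$sample_id))
    keep <- logical(n)
    for (i in seq_len(n)) {
        v <- variants[i, ]
        r1 <- v$alt_reads >= cfg@minAltReads
        r2 <- v$tumor_af > cfg@maxTumorAFDrop
        same <- variants$chrom == v$chrom & variants$pos == v$pos &
            variants$ref == v$ref & variants$alt == v$alt
        r3 <- length(unique(variants$sample_id[same])) / nSamp <
            cfg@maxCohortFraction
        r4 <- TRUE
        if (nchar(v$ref) != nchar(v$alt)) {
            others <- variants$sample_id == v$sample_id &
                variants$chrom == v$chrom &
                nchar(variants$ref) != nchar(variants$alt) &
                seq_len(n) != i
            if (any(others) &&
                any(abs(variants$pos[others] - v$pos) <= cfg@indelWindowBp))
                r4 <- FALSE
        }
        keep[i] <- r1 && r2 && r3 && r4
    }
    keep
}

bruteForceStrictFilter <- function(variants, cfg = variantFilterConfig()) {
    vapply(seq_len(nrow(variants)), function(i) {
        v <- variants[i, ]
        !(v$variant_class %in% cfg@removedClassesStrict) &&
            v$pop_af_max <= cfg@maxPopAF &&
            v$cadd_phred >= cfg@minCaddPhred &&
            !(!is.na(v$polyphen) && v$polyphen == "benign") &&
            !(!is.na(v$sift) && v$sift == "tolerated") &&
            !(!is.na(v$condel) && v$condel == "neutral") &&
            v$impact %in% cfg@allowedImpacts
    }, logical(1))
}

# random fusion-call table mixing whitelist, known and unrelated genes
randomFusionTable <- function(n, seed) {
    set.seed(seed)
    rules <- defaultFusionRules()
    pool <- c(rules@whitelist,
              sprintf("ZZ%03d", 1:60))
    g5 <- sample(pool, n, replace = TRUE)
    g3 <- vapply(g5, function(g) sample(setdiff(pool, g), 1), character(1))
    data.frame(sample_id = sample(sprintf("S%02d", 1:20), n, replace = TRUE),
               gene5 = g5, gene3 = unname(g3),
               breakpoint5 = "1:1", breakpoint3 = "2:2",
               split_reads = sample(0:20, n, replace = TRUE),
               spanning_reads = sample(0:10, n, replace = TRUE),
               stringsAsFactors = FALSE)
}
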