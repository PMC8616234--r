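# Synthetic cohort generator: determinism, moment structure, ground truth.

smallConfig <- function(seed = 1, ...) {
    cohortConfig(
        subgroups = list(
            subgroupSpec("A", 6, definingFusion = c("ETV6", "RUNX1"),
                         nSignatureGenes = 20),
            subgroupSpec("B", 6, definingHotspot = c("PAX5", "p.P80R"),
                         nSignatureGenes = 20)),
        nGenes = 120L, seed = seed, ...)
}

test_that("identical config and seed give byte-identical outputs", {
    cfg <- smallConfig(seed = 9)
    expect_identical(SummarizedExperiment::assay(simulateExpression(cfg)),
                     SummarizedExperiment::assay(simulateExpression(cfg)))
    expect_identical(simulateFusionCalls(cfg), simulateFusionCalls(cfg))
    expect_identical(simulateVariants(cfg), simulateVariants(cfg))
    expect_identical(
        SummarizedExperiment::assay(simulatePairedTubes(seed = 4)),
        SummarizedExperiment::assay(simulatePairedTubes(seed = 4)))
})

test_that("counts follow the configured NB mean-variance relationship", {
    # one subgroup, flat signature, fixed depth: per-gene NB moments are
    # checked against large-sample moment estimates
    cfg <- cohortConfig(
        subgroups = list(subgroupSpec("A", 400, nSignatureGenes = 5,
                                      signatureLog2FC = 0,
                                      definingFusion = c("X", "Y"),
                                      blastFraction = 1)),
        nGenes = 60L, gcBiasSlope = 0,
        librarySizeRange = c(1e8, 1e8), nbDispersion = 0.1, seed = 3)
    se <- simulateExpression(cfg)
    m <- SummarizedExperiment::assay(se)
    expect_true(all(m >= 0))
    expect_true(all(m == floor(m)))
    mu <- S4Vectors::metadata(se)$groundTruth$expectedMean[, 1]
    empMean <- rowMeans(m)
    empVar <- apply(m, 1L, var)
    idx <- which(mu > 50)
    expect_gt(length(idx), 10)
    expectedVar <- mu[idx] + 0.1 * mu[idx]^2
    # sample mean within 3 standard errors of the planted mean
    se3 <- 3 * sqrt(expectedVar / ncol(m))
    expect_gt(mean(abs(empMean[idx] - mu[idx]) <= se3), 0.95)
    # variance tracks mu + alpha mu^2
    expect_lt(median(abs(empVar[idx] / expectedVar - 1)), 0.35)
})

test_that("zero signature effect plants no DE genes and equal means", {
    cfg <- cohortConfig(
        subgroups = list(
            subgroupSpec("A", 30, definingFusion = c("E", "R"),
                         nSignatureGenes = 20, signatureLog2FC = 0),
            subgroupSpec("B", 30, definingFusion = c("B", "A1"),
                         nSignatureGenes = 20, signatureLog2FC = 0)),
        nGenes = 100L, gcBiasSlope = 0,
        librarySizeRange = c(1e8, 1e8), seed = 5)
    se <- simulateExpression(cfg)
    truth <- S4Vectors::metadata(se)$groundTruth$signature
    expect_identical(nrow(truth$A), 0L)
    expect_identical(nrow(truth$B), 0L)
    m <- SummarizedExperiment::assay(se)
    grp <- S4Vectors::metadata(se)$groundTruth$subtype == "A"
    mA <- rowMeans(m[, grp]); mB <- rowMeans(m[, !grp])
    # relative group difference small for expressed genes
    idx <- (mA + mB) / 2 > 50
    expect_lt(max(abs(log2((mA[idx] + 1) / (mB[idx] + 1)))), 0.5)
})

test_that("fusion support scales linearly with blast fraction", {
    mk <- function(bf) cohortConfig(
        subgroups = list(subgroupSpec("A", 200,
                                      definingFusion = c("ETV6", "RUNX1"),
                                      nSignatureGenes = 5,
                                      blastFraction = bf)),
        nGenes = 50L, librarySizeRange = c(1e8, 1e8),
        noiseFusionRate = 0, seed = 7)
    high <- simulateFusionCalls(mk(1.0))
    low <- simulateFusionCalls(mk(0.07))
    mh <- mean(high$calls$split_reads + high$calls$spanning_reads)
    ml <- mean(low$calls$split_reads + low$calls$spanning_reads)
    expect_equal(mh / ml, 1 / 0.07, tolerance = 0.1)
})

test_that("zero fusion noise emits exactly the true fusion set", {
    cfg <- cohortConfig(
        subgroups = list(subgroupSpec("A", 20,
                                      definingFusion = c("ETV6", "RUNX1"),
                                      nSignatureGenes = 5)),
        nGenes = 50L, noiseFusionRate = 0, seed = 2)
    fc <- simulateFusionCalls(cfg)
    expect_true(all(fc$truth$class %in% c("true", "dropout")))
    trueSet <- fc$truth[fc$truth$class == "true", c("sample_id", "gene5",
                                                    "gene3")]
    expect_identical(fc$calls[, c("sample_id", "gene5", "gene3")],
                     trueSet)
})

test_that("expected fusion support is non-decreasing in blast and depth", {
    mk <- function(bf, lib) cohortConfig(
        subgroups = list(subgroupSpec("A", 100,
                                      definingFusion = c("ETV6", "RUNX1"),
                                      nSignatureGenes = 5,
                                      blastFraction = bf)),
        nGenes = 50L, librarySizeRange = c(lib, lib),
        noiseFusionRate = 0, seed = 13)
    meanSupp <- function(cfg) {
        fc <- simulateFusionCalls(cfg)
        sum(fc$calls$split_reads + fc$calls$spanning_reads) /
            (nrow(fc$calls) + sum(fc$truth$class == "dropout"))
    }
    byBlast <- vapply(c(0.07, 0.2, 0.33, 1.0),
                      function(b) meanSupp(mk(b, 1e8)), numeric(1))
    expect_true(all(diff(byBlast) > 0))
    byDepth <- vapply(c(5e7, 1e8, 1.5e8),
                      function(l) meanSupp(mk(1.0, l)), numeric(1))
    expect_true(all(diff(byDepth) > 0))
})

test_that("with all variant noise off only drivers are emitted", {
    cfg <- smallConfig(seed = 21, editingExcess = 0, passengerRate = 0,
                       artifactRate = 0, artifactCooccurrenceFraction = 0)
    v <- simulateVariants(cfg)
    expect_true(all(v$truth$class == "driver"))
    expect_identical(nrow(v$variants), 6L)   # one per hotspot-subgroup sample
    expect_true(all(v$variants$gene == "PAX5"))
})

test_that("each planted artifact violates exactly its named rule", {
    cfg <- smallConfig(seed = 22, editingExcess = 0, passengerRate = 0,
                       artifactRate = 4)
    out <- simulateVariants(cfg)
    v <- out$variants
    tr <- out$truth
    cfgF <- variantFilterConfig()
    callerKeep <- bruteForceCallerFilter(v, cfgF)
    strictKeep <- bruteForceStrictFilter(v, cfgF)
    callerRules <- c("low_alt_reads", "low_tumor_af", "cohort_recurrent",
                     "indel_cluster")
    for (i in which(tr$class == "artifact")) {
        rule <- tr$violated_rule[i]
        if (rule %in% callerRules) {
            expect_false(callerKeep[i])
            expect_true(strictKeep[i])
        } else {
            expect_true(callerKeep[i])
            expect_false(strictKeep[i])
        }
    }
    # drivers pass everything
    expect_true(all(callerKeep[tr$class == "driver"]))
    expect_true(all(strictKeep[tr$class == "driver"]))
})

test_that("editing-only output is pure T>C in the collapsed spectrum", {
    cfg <- smallConfig(seed = 23, editingExcess = 10, passengerRate = 0,
                       artifactRate = 0, artifactCooccurrenceFraction = 0)
    out <- simulateVariants(cfg)
    ed <- out$variants[out$truth$class == "editing", ]
    expect_gt(nrow(ed), 50)
    sp <- substitutionSpectrum(ed)
    coll <- colSums(sp$collapsed)
    expect_identical(sum(coll), sum(coll["T>C"]))
    expect_true(all(ed$tumor_af >= 0.1 & ed$tumor_af <= 0.6))
})

test_that("paired tubes share patient baselines and honour a zero effect", {
    se0 <- simulatePairedTubes(nPatients = 4, nGenes = 200,
                               tubeLog2FC = 0, seed = 8)
    truth <- S4Vectors::metadata(se0)$groundTruth$tubeEffectGenes
    expect_identical(nrow(truth), 0L)
    cd <- SummarizedExperiment::colData(se0)
    expect_true(all(table(cd$patient, cd$condition) == 1L))
    expect_error(simulatePairedTubes(nPatients = 1), "nPatients")
})

test_that("isoform counts conserve gene totals and recover planted usage", {
    cfg <- smallConfig(seed = 31)
    se <- simulateExpression(cfg)
    m <- SummarizedExperiment::assay(se)
    iso <- simulateIsoformCounts(m, seed = 41)
    sums <- rowsum(iso$counts, iso$map$gene_id)
    expect_true(all(sums[rownames(m), ] == m))

    # planted swap on a 2-isoform gene
    nIso <- table(iso$map$gene_id)
    gene2 <- names(nIso)[nIso == 2][1]
    grpSamples <- colnames(m)[1:6]
    shifted <- simulateIsoformCounts(
        m, usageShifts = list(list(gene = gene2, samples = grpSamples,
                                   proportions = c(0.2, 0.8))),
        seed = 41)
    isoIds <- shifted$map$isoform_id[shifted$map$gene_id == gene2]
    tot <- colSums(shifted$counts[isoIds, grpSamples])
    phat <- sum(shifted$counts[isoIds[1], grpSamples]) / sum(tot)
    se3 <- 3 * sqrt(0.2 * 0.8 / sum(tot))
    expect_lt(abs(phat - 0.2), se3 + 0.02)

    # shift on a single-isoform gene is a configuration error
    gene1 <- names(nIso)[nIso == 1][1]
    expect_error(simulateIsoformCounts(
        m, usageShifts = list(list(gene = gene1, samples = grpSamples,
                                   proportions = c(1))),
        seed = 41), "single-isoform")
})
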