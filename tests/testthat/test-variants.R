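# Variant filter cascade, hotspot classification, spectrum, co-occurrence.

mkVar <- function(sample = "S1", chrom = "1", pos = 1000L, ref = "A",
                  alt = "G", alt_reads = 20L, tumor_af = 0.4,
                  pop_af_max = 0, cadd = 25,
                  class = "missense", impact = "MODERATE",
                  polyphen = "probably_damaging", sift = "deleterious",
                  condel = "deleterious", gene = "GENE1",
                  protein_change = NA_character_) {
    data.frame(sample_id = sample, chrom = chrom, pos = pos, ref = ref,
               alt = alt, alt_reads = alt_reads, tumor_af = tumor_af,
               pop_af_max = pop_af_max, cadd_phred = cadd,
               consequence = "missense_variant", variant_class = class,
               impact = impact, polyphen = polyphen, sift = sift,
               condel = condel, gene = gene,
               protein_change = protein_change,
               is_indel = nchar(ref) != nchar(alt),
               stringsAsFactors = FALSE)
}

test_that("caller-filter boundaries behave as specified", {
    # padding variants so recurrence (1 sample of 3) never fires
    pad <- rbind(mkVar("S2", pos = 9e6L), mkVar("S3", pos = 9.5e6L))

    five <- rbind(mkVar(alt_reads = 5L), pad)
    out <- applyCallerFilters(five)
    expect_true("low_alt_reads" %in% out$dropped$drop_reason)
    six <- rbind(mkVar(alt_reads = 6L), pad)
    expect_identical(nrow(applyCallerFilters(six)$retained), 3L)

    afAt <- rbind(mkVar(tumor_af = 0.1), pad)
    expect_identical(applyCallerFilters(afAt)$dropped$drop_reason,
                     "low_tumor_af")
    afAbove <- rbind(mkVar(tumor_af = 0.100001), pad)
    expect_identical(nrow(applyCallerFilters(afAbove)$retained), 3L)

    # indel pair at distance exactly 20: both dropped; at 21: both kept
    at20 <- rbind(mkVar(pos = 1000L, ref = "A", alt = "AT"),
                  mkVar(pos = 1020L, ref = "C", alt = "CG"), pad)
    out20 <- applyCallerFilters(at20)
    expect_identical(sum(out20$dropped$drop_reason == "indel_cluster"), 2L)
    at21 <- rbind(mkVar(pos = 1000L, ref = "A", alt = "AT"),
                  mkVar(pos = 1021L, ref = "C", alt = "CG"), pad)
    expect_identical(nrow(applyCallerFilters(at21)$retained), 4L)
})

test_that("cohort recurrence uses the raw input at the 40% threshold", {
    # same variant in 2 of 5 samples: 40% -> dropped
    rec <- do.call(rbind, c(
        lapply(c("S1", "S2"), function(s) mkVar(s, pos = 500L)),
        lapply(c("S3", "S4", "S5"),
               function(s) mkVar(s, pos = 1000L + match(s, paste0("S", 3:5)) * 100L))))
    out <- applyCallerFilters(rec)
    expect_identical(sum(out$dropped$drop_reason == "cohort_recurrent"), 2L)
    # in 1 of 5 samples (20%): kept; and a variant failing rule 1 still
    # counts as a carrier for rule 3 (computed pre-filter)
    mix <- rbind(mkVar("S1", pos = 500L, alt_reads = 2L),
                 mkVar("S2", pos = 500L),
                 mkVar("S3", pos = 700L), mkVar("S4", pos = 800L),
                 mkVar("S5", pos = 900L))
    out2 <- applyCallerFilters(mix)
    reasons <- out2$dropped$drop_reason
    expect_setequal(reasons, c("low_alt_reads", "cohort_recurrent"))
})

test_that("annotation-filter boundaries behave as specified", {
    silent <- mkVar(class = "silent")
    expect_identical(
        applyAnnotationFilters(silent, mode = "strict")$dropped$drop_reason,
        "removed_class")
    expect_identical(
        nrow(applyAnnotationFilters(silent, mode = "spectrum")$retained),
        1L)

    good <- mkVar(pop_af_max = 5e-5, cadd = 20)
    expect_identical(
        nrow(applyAnnotationFilters(good, mode = "strict")$retained), 1L)

    lowCadd <- mkVar(cadd = 14.9)
    expect_identical(
        applyAnnotationFilters(lowCadd, mode = "strict")$dropped$drop_reason,
        "low_cadd")
    atCadd <- mkVar(cadd = 15)
    expect_identical(
        nrow(applyAnnotationFilters(atCadd, mode = "strict")$retained), 1L)

    # population AF: exactly 1e-4 retained, above removed (also in
    # spectrum mode)
    atAF <- mkVar(pop_af_max = 1e-4)
    expect_identical(
        nrow(applyAnnotationFilters(atAF, mode = "strict")$retained), 1L)
    aboveAF <- mkVar(pop_af_max = 1.1e-4)
    for (mode in c("strict", "spectrum"))
        expect_identical(
            applyAnnotationFilters(aboveAF, mode = mode)$dropped$drop_reason,
            "high_pop_af")

    # predictor-wise benign rule; missing labels do not count
    expect_identical(
        applyAnnotationFilters(mkVar(sift = "tolerated"),
                               mode = "strict")$dropped$drop_reason,
        "benign_prediction")
    expect_identical(
        nrow(applyAnnotationFilters(mkVar(polyphen = NA, sift = NA,
                                          condel = NA),
                                    mode = "strict")$retained), 1L)
    expect_identical(
        applyAnnotationFilters(mkVar(impact = "LOW"),
                               mode = "strict")$dropped$drop_reason,
        "low_impact")
})

test_that("the cascade matches brute-force predicates on 1000 synthetic variants", {
    cfg <- cohortConfig(
        subgroups = list(subgroupSpec("B", 30,
                                      definingHotspot = c("PAX5", "p.P80R"),
                                      nSignatureGenes = 5)),
        nGenes = 60L, editingExcess = 15, passengerRate = 10,
        artifactRate = 8, seed = 99)
    v <- simulateVariants(cfg)$variants
    expect_gt(nrow(v), 1000)
    v <- v[seq_len(max(1000, nrow(v))), ]
    out <- applyCallerFilters(v)
    keep <- bruteForceCallerFilter(v)
    expect_identical(out$retained$variant_id, v$variant_id[keep])
    strict <- applyAnnotationFilters(out$retained, mode = "strict")
    keep2 <- bruteForceStrictFilter(out$retained)
    expect_identical(strict$retained$variant_id,
                     out$retained$variant_id[keep2])
    # idempotence of both stages
    expect_identical(applyCallerFilters(out$retained)$retained,
                     out$retained)
    expect_identical(
        applyAnnotationFilters(strict$retained, mode = "strict")$retained,
        strict$retained)
})

test_that("hotspot classification assigns, skips and flags conflicts", {
    hs <- c("PAX5:p.P80R" = "PAX5 P80R", "IKZF1:p.N159Y" = "IKZF1 N159Y")
    one <- mkVar(gene = "PAX5", protein_change = "p.P80R")
    expect_identical(classifyByHotspot(one, hs)$subtype, "PAX5 P80R")
    none <- mkVar(gene = "TP53", protein_change = "p.R175H")
    expect_true(is.na(classifyByHotspot(none, hs)$subtype))
    both <- rbind(mkVar(gene = "PAX5", protein_change = "p.P80R"),
                  mkVar(gene = "IKZF1", protein_change = "p.N159Y",
                        pos = 2000L))
    out <- classifyByHotspot(both, hs)
    expect_true(is.na(out$subtype) && out$conflict)
})

test_that("hotspot-defined samples are recovered at 100% through the cascade", {
    cfg <- cohortConfig(
        subgroups = list(
            subgroupSpec("PAX5 P80R", 12,
                         definingHotspot = c("PAX5", "p.P80R"),
                         nSignatureGenes = 5),
            subgroupSpec("Other", 12, nSignatureGenes = 5)),
        nGenes = 60L, seed = 44)
    v <- simulateVariants(cfg)
    kept <- applyCallerFilters(v$variants)$retained
    kept <- applyAnnotationFilters(kept, mode = "strict")$retained
    cl <- classifyByHotspot(kept)
    truth <- S4Vectors::metadata(simulateExpression(cfg))$groundTruth$subtype
    hotspotSamples <- names(truth)[truth == "PAX5 P80R"]
    got <- cl$sample_id[!is.na(cl$subtype) & cl$subtype == "PAX5 P80R"]
    expect_setequal(got, hotspotSamples)
})

test_that("substitution spectra collapse complements and conserve totals", {
    v <- data.frame(sample_id = "S1", ref = c("T", "A"),
                    alt = c("C", "G"), stringsAsFactors = FALSE)
    sp <- substitutionSpectrum(v)
    expect_identical(unname(sp$collapsed[1, "T>C"]), 2L)
    expect_identical(sum(sp$collapsed), 2L)
    expect_identical(unname(sp$directional[1, "T>C"]), 1L)
    expect_identical(unname(sp$directional[1, "A>G"]), 1L)

    set.seed(8)
    bases <- c("A", "C", "G", "T")
    rv <- data.frame(sample_id = sample(c("S1", "S2"), 60, replace = TRUE),
                     ref = sample(bases, 60, replace = TRUE),
                     stringsAsFactors = FALSE)
    rv$alt <- vapply(rv$ref, function(r) sample(setdiff(bases, r), 1),
                     character(1))
    sp1 <- substitutionSpectrum(rv)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- rv
    rc$ref <- unname(comp[rv$ref]); rc$alt <- unname(comp[rv$alt])
    sp2 <- substitutionSpectrum(rc)
    expect_identical(sp1$collapsed, sp2$collapsed)
    expect_identical(sum(sp1$collapsed), nrow(rv))

    # indels and MNPs excluded from SBS classes but typed
    mix <- data.frame(sample_id = "S1",
                      ref = c("A", "AT", "ATG", "A"),
                      alt = c("G", "GC", "CCA", "AT"),
                      stringsAsFactors = FALSE)
    spm <- substitutionSpectrum(mix)
    expect_identical(sum(spm$collapsed), 1L)
    expect_identical(unname(spm$variantType[1, ]), c(1L, 1L, 1L, 1L))
})

test_that("co-occurrence matches a brute-force double loop and its bound", {
    set.seed(10)
    toy <- data.frame(
        sample_id = sample(sprintf("S%d", 1:8), 50, replace = TRUE),
        gene = sample(LETTERS[1:6], 50, replace = TRUE),
        stringsAsFactors = FALSE)
    out <- topMutatedAndCooccurrence(toy)
    co <- out$cooccurrence
    genes <- colnames(co)
    for (a in genes) for (b in genes) {
        sa <- unique(toy$sample_id[toy$gene == a])
        sb <- unique(toy$sample_id[toy$gene == b])
        expect_identical(unname(co[a, b]), length(intersect(sa, sb)))
    }
    offDiag <- co; diag(offDiag) <- 0L
    expect_true(all(offDiag <= outer(diag(co), diag(co), pmin)))
    expect_identical(co, t(co))

    single <- data.frame(sample_id = "S1", gene = c("A", "B"),
                         stringsAsFactors = FALSE)
    co1 <- topMutatedAndCooccurrence(single)$cooccurrence
    expect_identical(unname(co1["A", "B"]), 1L)
    expect_identical(unname(diag(co1)), c(1L, 1L))
})

test_that("a single-sample cohort triggers the recurrence warning", {
    expect_warning(applyCallerFilters(mkVar()), "single-sample")
})
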