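# Normalization, NB differential expression, panel sweep, embedding,
# co-clustering assignment and tier integration.

test_that("GC normalization removes a planted trend and preserves means", {
    set.seed(3)
    ng <- 2000; n <- 8
    gc <- runif(ng, 0.3, 0.7)
    base <- rlnorm(ng, log(100), 1)
    # planted monotone GC trend: 2 log2-units per unit GC
    mu <- outer(base, rep(1, n)) * 2^(2 * (gc - mean(gc)))
    counts <- matrix(rnbinom(ng * n, mu = mu, size = 10), ng, n,
                     dimnames = list(paste0("g", 1:ng), paste0("s", 1:n)))
    out <- gcNormalize(counts, gc)
    v <- normValues(out)
    rho <- cor(rowMeans(v), gc, method = "spearman")
    expect_lt(abs(rho), 0.05)
    # per-sample mean log-signal preserved
    expect_lt(max(abs(colMeans(v) - colMeans(log2(counts + 0.5)))), 1e-6)

    # null bias: output close to input
    mu0 <- outer(base, rep(1, n))
    counts0 <- matrix(rnbinom(ng * n, mu = mu0, size = 10), ng, n,
                      dimnames = dimnames(counts))
    v0 <- normValues(gcNormalize(counts0, gc))
    delta <- abs(v0 - log2(counts0 + 0.5))
    expect_gt(mean(delta < 0.1), 0.95)

    expect_warning(gcNormalize(counts0, rep(0.5, ng)), "constant GC")
})

test_that("variance stabilization is monotone and absorbs depth", {
    set.seed(4)
    m <- matrix(rpois(400, 200) + 1L, 40, 10,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
    v <- normValues(varianceStabilize(m))
    # strictly monotone within sample
    for (j in 1:5) {
        ord <- order(m[, j])
        expect_true(all(diff(v[ord, j]) >= 0))
    }
    # doubling one sample: its transformed values unchanged up to the
    # 2^(1/n) reference shift of the median-of-ratios size factors
    m2 <- m; m2[, 1] <- m2[, 1] * 2L
    v2 <- normValues(varianceStabilize(m2))
    expect_lt(max(abs(v2[, 1] - v[, 1])), log2(2) / ncol(m) + 0.01)

    # sd of transformed values far more stable than raw counts
    set.seed(5)
    mu <- rep(10^seq(1, 4, length.out = 60), each = 1)
    sim <- matrix(rnbinom(60 * 50, mu = rep(mu, 50), size = 10), 60, 50,
                  dimnames = list(paste0("g", 1:60), paste0("s", 1:50)))
    vs <- normValues(varianceStabilize(sim))
    sdRaw <- apply(sim, 1, sd)
    sdVst <- apply(vs, 1, sd)
    expect_gt(max(sdRaw) / min(sdRaw), 10)
    expect_lt(max(sdVst) / min(sdVst), 3)

    zero <- m; zero[, 2] <- 0L
    expect_error(varianceStabilize(zero), "s2")
})

test_that("differential expression is calibrated, recovers effects and is antisymmetric", {
    set.seed(42)
    ng <- 2000; n <- 60
    mu <- rlnorm(ng, log(80), 1.2)
    counts <- matrix(rnbinom(ng * n, mu = rep(mu, n), size = 10), ng, n,
                     dimnames = list(sprintf("g%d", 1:ng),
                                     sprintf("s%d", 1:n)))
    mask <- rep(c(TRUE, FALSE), c(20, 40))
    res <- differentialExpression(counts, mask)
    expect_gt(mean(res$pvalue < 0.05, na.rm = TRUE), 0.03)
    expect_lt(mean(res$pvalue < 0.05, na.rm = TRUE), 0.07)

    # planted 4-fold genes at mean 100
    idx <- which(mu > 50 & mu < 200)[1:100]
    mu2 <- matrix(rep(mu, n), ng, n)
    mu2[idx, mask] <- mu2[idx, mask] * 4
    counts2 <- matrix(rnbinom(ng * n, mu = mu2, size = 10), ng, n,
                      dimnames = dimnames(counts))
    res2 <- differentialExpression(counts2, mask)
    lfc <- res2$log2FoldChange[match(sprintf("g%d", idx), res2$gene)]
    expect_lt(abs(median(lfc) - 2), 0.3)

    # swapping groups negates every log2FC
    resSwap <- differentialExpression(counts2, !mask)
    expect_lt(max(abs(res2$log2FoldChange + resSwap$log2FoldChange),
                  na.rm = TRUE), 1e-6)

    expect_error(differentialExpression(counts, rep(TRUE, n)),
                 "non-empty")
})

test_that("NB-Wald estimates agree with an independent DESeq2 fit", {
    skip_if_not_installed("DESeq2")
    set.seed(77)
    ng <- 300; n <- 24
    mu <- rlnorm(ng, log(100), 1)
    mask <- rep(c(TRUE, FALSE), each = 12)
    fc <- rep(1, ng); fc[1:30] <- 4; fc[31:60] <- 0.25
    mu2 <- outer(mu, rep(1, n)); mu2[, mask] <- mu2[, mask] * fc
    counts <- matrix(rnbinom(ng * n, mu = mu2, size = 10), ng, n,
                     dimnames = list(sprintf("g%d", 1:ng),
                                     sprintf("s%d", 1:n)))
    mine <- differentialExpression(counts, mask)
    dds <- DESeq2::DESeqDataSetFromMatrix(
        counts, S4Vectors::DataFrame(grp = factor(ifelse(mask, "b", "a"))),
        ~ grp)
    dres <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
    common <- intersect(mine$gene, rownames(dres))
    a <- mine$log2FoldChange[match(common, mine$gene)]
    b <- dres[common, "log2FoldChange"]
    expect_gt(cor(a, b, use = "complete.obs"), 0.98)
    pa <- -log10(mine$pvalue[match(common, mine$gene)])
    pb <- -log10(dres[common, "pvalue"])
    ok <- is.finite(pa) & is.finite(pb)
    expect_gt(cor(pa[ok], pb[ok], method = "spearman"), 0.9)
})

test_that("the default sweep grid has 55 increasing sizes", {
    cfg <- panelSweepConfig()
    expect_identical(length(cfg@sizes), 55L)
    expect_identical(cfg@sizes, seq(300L, 3000L, by = 50L))
})

test_that("panel construction recovers planted markers and is reproducible", {
    fx <- defaultCohortFixture()
    pf <- defaultPanelFixture()
    p <- pf$panel
    sig <- S4Vectors::metadata(fx$se)$groundTruth$signature
    for (g in names(sig)) {
        expect_gt(mean(sig[[g]]$gene %in% p$degUnion), 0.8)
        expect_gt(mean(sig[[g]]$gene %in% p$panel), 0.8)
    }
    # subgroups below the size threshold contribute no comparison
    labels2 <- fx$labels
    small <- names(which(table(labels2) > 0))[1]
    keepIdx <- which(labels2 == small)
    labels2[keepIdx[-(1:2)]] <- NA   # leave 2 labelled samples
    p2 <- suppressWarnings(buildDegPanel(
        pf$m, pf$vst, labels2,
        panelSweepConfig(sizes = c(300L, 350L))))
    expect_false(small %in% names(p2$perSubgroup))

    # bit-for-bit reproducibility of the sweep table
    p3 <- suppressWarnings(buildDegPanel(pf$m, pf$vst, fx$labels,
                                         panelSweepConfig()))
    expect_identical(p$sweep, p3$sweep)
    expect_identical(p$panel, p3$panel)
})

test_that("embeddings are seeded, separate blobs, and guard perplexity", {
    set.seed(2)
    blob <- rbind(matrix(rnorm(40 * 5, 0, 0.1), 20),
                  matrix(rnorm(40 * 5, 10, 0.1), 20))
    rownames(blob) <- paste0("s", 1:40)
    lab <- rep(c("a", "b"), each = 20)
    co1 <- embedSamples(t(blob), perplexity = 5, maxIter = 500, seed = 6)
    co2 <- embedSamples(t(blob), perplexity = 5, maxIter = 500, seed = 6)
    expect_identical(co1, co2)
    expect_gt(separationScore(co1, lab), 0.8)

    um <- embedSamples(t(blob), method = "umap", seed = 6)
    expect_gt(separationScore(um, lab), 0.8)

    small <- t(blob[1:10, ])
    expect_warning(embedSamples(small, perplexity = 20, maxIter = 300,
                                seed = 1), "perplexity")
})

test_that("the separation score is isometry-invariant and needs two labels", {
    set.seed(9)
    co <- rbind(matrix(rnorm(20, 0, 0.2), 10),
                matrix(rnorm(20, 8, 0.2), 10))
    lab <- rep(c("a", "b"), each = 10)
    s0 <- separationScore(co, lab)
    expect_gt(s0, 0.9)
    theta <- 0.7
    rot <- co %*% matrix(c(cos(theta), -sin(theta), sin(theta),
                           cos(theta)), 2) + 5
    expect_equal(separationScore(rot, lab), s0, tolerance = 1e-10)
    # coincident clusters score near zero
    expect_lt(separationScore(rbind(co[1:10, ], co[1:10, ] +
                                        rnorm(20, 0, 0.2)), lab), 0.3)
    expect_error(separationScore(co, rep("a", 20)), "two labels")
})

test_that("co-clustering votes respect k, the majority threshold and truth", {
    # geometric toy: unknown near cluster a
    set.seed(12)
    m <- cbind(matrix(rnorm(100 * 10, 0, 0.1), 100),
               matrix(rnorm(100 * 10, 3, 0.1), 100),
               matrix(rnorm(100 * 2, 0, 0.1), 100))
    colnames(m) <- c(paste0("a", 1:10), paste0("b", 1:10), "u1", "u2")
    labels <- c(rep("A", 10), rep("B", 10), NA, NA)
    out <- assignByCoclustering(m, labels, k = 10)
    expect_identical(out$subtype, c("A", "A"))
    expect_error(assignByCoclustering(m, labels, k = 30), "labelled")

    # majority threshold in correlation geometry: the 10 nearest
    # neighbours carry controlled label votes
    fakeVotes <- function(nA) {
        set.seed(20)
        u <- rnorm(80)
        mkcol <- function(alpha) alpha * u + sqrt(1 - alpha^2) * rnorm(80)
        near <- sapply(seq(0.95, 0.86, length.out = 10), mkcol)
        far <- sapply(rep(0.05, 20), mkcol)
        mm <- cbind(near, far, u)
        colnames(mm) <- c(paste0("n", 1:10), paste0("f", 1:20), "u")
        labs <- c(rep("A", nA), rep("B", 3), rep("C", 10 - nA - 3),
                  rep(c("B", "C"), 10), NA)
        assignByCoclustering(mm, labs, k = 10, minFrac = 0.5)
    }
    expect_identical(fakeVotes(5)$subtype, "A")   # 5/10 majority
    expect_true(is.na(fakeVotes(4)$subtype))      # 4/10 below threshold
})

test_that("co-clustering recovers expression-defined unknowns in the cohort", {
    fx <- defaultCohortFixture()
    pf <- defaultPanelFixture()
    panelMat <- normValues(pf$vst)[pf$panel$panel, ]
    out <- assignByCoclustering(panelMat, fx$labels, k = 10)
    truthUnknown <- fx$truth[out$sample_id]
    acc <- mean(out$subtype == truthUnknown, na.rm = TRUE)
    expect_gt(acc, 0.9)

    # leave-one-out self-consistency over labelled samples
    labelled <- which(!is.na(fx$labels))
    hits <- vapply(labelled, function(i) {
        l2 <- fx$labels; l2[i] <- NA
        res <- assignByCoclustering(panelMat, l2, k = 10)
        isTRUE(res$subtype[res$sample_id ==
                               colnames(panelMat)[i]] == fx$truth[i])
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("tier integration follows precedence and flags conflicts", {
    fus <- data.frame(sample_id = "S1", subtype = "BCR-ABL1",
                      stringsAsFactors = FALSE)
    hot <- data.frame(sample_id = c("S1", "S2"),
                      subtype = c("PAX5 P80R", "PAX5 P80R"),
                      stringsAsFactors = FALSE)
    cocl <- data.frame(sample_id = c("S1", "S3"),
                       subtype = c("DUX4-r", "DUX4-r"),
                       confidence = c(0.9, 0.7),
                       stringsAsFactors = FALSE)
    out <- integrateAssignments(c("S1", "S2", "S3", "S4"), fus, hot, cocl)
    expect_identical(out$subtype, c("BCR-ABL1", "PAX5 P80R", "DUX4-r",
                                    NA))
    expect_identical(out$evidence, c("fusion", "hotspot", "co-clustering",
                                     "unassigned"))
    expect_identical(out$conflict, c(TRUE, FALSE, FALSE, FALSE))
    expect_equal(out$confidence, c(1, 1, 0.7, NA))
})
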