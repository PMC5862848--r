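test_that("features are distinct (sequence, mods, charge) triples per sample", {
    psms <- data.frame(
        protein_id = c("A", "A", "A", "A", "B"),
        sequence = c("PEPK", "PEPK", "PEPK", "PEPK", "CATK"),
        mods = c("", "", "2:ox", "", ""),
        charge = c(2, 3, 2, 2, 2),
        sample_id = c("s1", "s1", "s1", "s1", "s2"),
        condition = c("probe", "probe", "probe", "probe", "control"),
        replicate = c("R1", "R1", "R1", "R1", "R1"))
    se <- countFeatures(psms)
    counts <- SummarizedExperiment::assay(se)
    # same peptide at charge 2 and 3 plus a modified form: 3 features;
    # the duplicate PSM of an identical form does not add
    expect_equal(counts["A", "s1"], 3L)
    expect_equal(counts["B", "s2"], 1L)
    expect_equal(counts["B", "s1"], 0L)
})

test_that("sparse proteins are discarded by the minimum-feature rule", {
    m <- matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 5, 5, 5, 5), nrow = 3,
        byrow = TRUE)
    rownames(m) <- c("two", "three", "many")
    se <- featureCountMatrix(m, rep(c("control", "probe"), each = 2),
        rep(c("R1", "R2"), 2))
    kept <- filterMinFeatures(se, 3)
    expect_equal(rownames(kept), c("three", "many"))
    empty <- filterMinFeatures(se[rowSums(m) < 0, ], 3)
    expect_equal(nrow(empty), 0L)
})

test_that("log2-CPM transform matches the defining formula", {
    set.seed(51)
    counts <- matrix(rnbinom(200 * 6, mu = 50, size = 5), 200, 6)
    counts[1, 1] <- 0
    rownames(counts) <- paste0("P", 1:200)
    se <- featureCountMatrix(counts, rep(c("control", "probe"),
        each = 3), rep(paste0("R", 1:3), 2))
    vt <- voomTransform(se)
    lib <- colSums(counts)
    expect_equal(vt$y[1, 1], log2(0.5 / (lib[1] + 1) * 1e6),
        ignore_attr = TRUE)
    expect_equal(vt$y[5, 4],
        log2((counts[5, 4] + 0.5) / (lib[4] + 1) * 1e6),
        ignore_attr = TRUE)
    expect_true(all(vt$weights > 0))
    # invariant under permutation of protein order
    perm <- sample(200)
    vtp <- voomTransform(se[perm, ])
    expect_equal(vtp$y, vt$y[perm, ])
    expect_equal(vtp$weights, vt$weights[perm, ], tolerance = 1e-12)
})

test_that("zero count with library size 999999 transforms to exactly -1", {
    counts <- rbind(rep(0L, 4), rep(999999L, 4))
    rownames(counts) <- c("zero", "big")
    se <- featureCountMatrix(counts, c("control", "control", "probe",
        "probe"), c("R1", "R2", "R1", "R2"))
    vt <- voomTransform(se)
    expect_equal(unname(vt$y["zero", 1]), -1)
})

test_that("moderated fit agrees with the direct-formula oracle", {
    set.seed(52)
    counts <- matrix(rnbinom(5 * 6, mu = 60, size = 5), 5, 6)
    rownames(counts) <- paste0("P", 1:5)
    se <- featureCountMatrix(counts, rep(c("control", "probe"),
        each = 3), rep(paste0("R", 1:3), 2))
    vt <- voomTransform(se)
    # with only 5 proteins the log-variance spread can fall below its
    # sampling noise; both routes then take the common-variance limit
    fit <- suppressWarnings(moderatedT(vt))
    want <- oracleModeratedT(vt$y, vt$weights, vt$design)
    expect_equal(fit$log2FC, want$beta, tolerance = 1e-8)
    expect_equal(fit$s2, want$s2, tolerance = 1e-8)
    expect_equal(fit$s2_post, want$s2post, tolerance = 1e-6)
    expect_equal(fit$t, want$t, tolerance = 1e-6)
    expect_equal(attr(fit, "d0"), want$d0, tolerance = 1e-4)
})

test_that("moderated fit agrees with the reference implementation", {
    skip_if_not_installed("limma")
    set.seed(53)
    counts <- matrix(rnbinom(300 * 6, mu = 50, size = 5), 300, 6)
    counts[1:30, 4:6] <- rnbinom(30 * 3, mu = 400, size = 5)
    rownames(counts) <- paste0("P", 1:300)
    cond <- rep(c("control", "probe"), each = 3)
    se <- featureCountMatrix(counts, cond, rep(paste0("R", 1:3), 2))
    vt <- voomTransform(se)
    fit <- moderatedT(vt)
    design <- cbind(1, as.numeric(cond == "probe"))
    v <- limma::voom(counts, design, span = 0.5)
    eb <- limma::eBayes(limma::lmFit(v, design))
    expect_equal(unname(vt$y), unname(v$E), tolerance = 1e-10)
    expect_equal(unname(vt$weights), unname(v$weights),
        tolerance = 1e-8)
    expect_equal(fit$log2FC, unname(eb$coefficients[, 2]),
        tolerance = 1e-10)
    expect_equal(fit$t, unname(eb$t[, 2]), tolerance = 1e-8)
    expect_equal(fit$p, unname(eb$p.value[, 2]), tolerance = 1e-8)
    expect_equal(attr(fit, "d0"), eb$df.prior, tolerance = 1e-6)
})

test_that("prior-df limits recover the ordinary and pooled t-tests", {
    set.seed(54)
    counts <- matrix(rnbinom(100 * 6, mu = 50, size = 5), 100, 6)
    rownames(counts) <- paste0("P", 1:100)
    se <- featureCountMatrix(counts, rep(c("control", "probe"),
        each = 3), rep(paste0("R", 1:3), 2))
    vt <- voomTransform(se)
    # d0 = 0: the ordinary per-protein weighted t-test, recomputed
    # directly from the WLS formulas
    fit0 <- moderatedT(vt, priorDf = 0)
    expect_equal(fit0$s2_post, fit0$s2)
    expect_true(all(fit0$df_total == ncol(counts) - 2))
    X <- vt$design
    tOrd <- vapply(seq_len(nrow(counts)), function(i) {
        W <- diag(vt$weights[i, ])
        XtWX <- t(X) %*% W %*% X
        b <- solve(XtWX, t(X) %*% W %*% vt$y[i, ])
        r <- vt$y[i, ] - X %*% b
        s2 <- sum(vt$weights[i, ] * r^2) / (ncol(counts) - 2)
        b[2] / sqrt(solve(XtWX)[2, 2] * s2)
    }, numeric(1))
    expect_equal(fit0$t, tOrd, tolerance = 1e-9)
    # d0 = Inf: every protein shares one variance
    fitInf <- moderatedT(vt, priorDf = Inf, priorVar = 0.5)
    expect_true(all(abs(fitInf$s2_post - 0.5) < 1e-12))
    expect_equal(fitInf$t, fit0$t * sqrt(fit0$s2) / sqrt(0.5),
        tolerance = 1e-9)
})

test_that("mirrored conditions give zero fold change and p = 1", {
    set.seed(56)
    counts <- matrix(rnbinom(50 * 6, mu = 50, size = 5), 50, 6)
    counts[, 4:6] <- counts[, 1:3]
    rownames(counts) <- paste0("P", 1:50)
    vt <- voomTransform(featureCountMatrix(counts,
        rep(c("control", "probe"), each = 3),
        rep(paste0("R", 1:3), 2)))
    fit <- suppressWarnings(moderatedT(vt))
    expect_true(all(abs(fit$log2FC) < 1e-10))
    expect_true(all(fit$p > 1 - 1e-10))
})

test_that("BH adjustment matches the hand-computed step-up", {
    expect_equal(bhAdjust(0.04), 0.04)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_error(bhAdjust(c(0.5, 0)), "in \\(0, 1\\]")
    expect_error(bhAdjust(1.5), "in \\(0, 1\\]")
    # order-preserving
    set.seed(55)
    p <- runif(50)
    q <- bhAdjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("null simulations give calibrated type-I error", {
    cfg <- simConfig(nProteins = 500L)
    fp <- vapply(1:40, function(i) {
        se <- simulateCounts(cfg, seed = 6000 + i, nProteins = 500,
            enriched = rep(FALSE, 500))
        enr <- suppressWarnings(enrichmentAnalysis(se))
        mean(enr$p < 0.05)
    }, numeric(1))
    expect_gt(mean(fp), 0.02)
    expect_lt(mean(fp), 0.08)
})

test_that("planted enrichment is recovered with high power and precision", {
    cfg <- simConfig(nProteins = 500L)
    enriched <- rep(FALSE, 500)
    enriched[1:50] <- TRUE
    power <- prec <- numeric(5)
    for (i in 1:5) {
        se <- simulateCounts(cfg, seed = 7000 + i, nProteins = 500,
            enriched = enriched)
        enr <- suppressWarnings(enrichmentAnalysis(se))
        power[i] <- mean(enr$q[1:50] < 0.05)
        top20 <- order(enr$q, -abs(enr$log2FC))[1:20]
        prec[i] <- mean(top20 <= 50)
        # direction: zero-ish control counts with large probe counts
        expect_true(all(enr$log2FC[1:50][enr$q[1:50] < 0.05] > 0))
    }
    expect_gte(mean(power), 0.9)
    expect_gte(mean(prec), 0.95)
})

test_that("volcano table keeps all proteins and sorts by significance", {
    cfg <- simConfig(nProteins = 100L)
    se <- simulateCounts(cfg, seed = 61, nProteins = 100)
    enr <- suppressWarnings(enrichmentAnalysis(se))
    vol <- volcanoTable(enr)
    expect_equal(nrow(vol), nrow(enr))
    expect_true(all(diff(vol$q) >= -1e-12))
    expect_equal(vol$neg_log10_p, -log10(vol$p))
})
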