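remnantFix <- Modification("remnant", 387.194, "C")

test_that("fragment ions obey counting and mass conservation", {
    ions <- fragmentIons("ACDEK")
    expect_equal(nrow(ions), 2 * 4)
    total <- peptideMass("ACDEK")
    for (i in 1:4) {
        b <- ions$neutral[ions$type == "b" & ions$index == i]
        y <- ions$neutral[ions$type == "y" & ions$index == 5 - i]
        expect_equal(b + y, total, tolerance = 1e-9)
    }
    expect_error(fragmentIons("A"), "length >= 2")
})

test_that("modified fragments shift by the remnant delta iff they contain the site", {
    mods <- data.frame(position = 2, delta = 387.194)
    plain <- fragmentIons("ACK")
    modded <- fragmentIons("ACK", mods)
    get <- function(x, type, i) x$mz[x$type == type & x$index == i]
    # b1 (A) and y1 (K) exclude the Cys: unshifted
    expect_equal(get(modded, "b", 1), get(plain, "b", 1))
    expect_equal(get(modded, "y", 1), get(plain, "y", 1))
    # b2 (AC) and y2 (CK) contain it: shifted by the delta
    expect_equal(get(modded, "b", 2), get(plain, "b", 2) + 387.194,
        tolerance = 1e-9)
    expect_equal(get(modded, "y", 2), get(plain, "y", 2) + 387.194,
        tolerance = 1e-9)
})

test_that("spectrum matching scores matched ions and breaks ties deterministically", {
    tol <- matchTolerance()
    candA <- list(sequence = "ACDEK",
        mods = data.frame(position = 2, delta = 387.194,
            name = "remnant"))
    ionsA <- fragmentIons(candA$sequence, candA$mods)
    spA <- Spectrum("s1", mz(peptideMass(candA$sequence, candA$mods), 2),
        2, data.frame(mz = ionsA$mz, intensity = 100))
    # candidate B shares the precursor but few fragments
    candB <- list(sequence = "CADEK",
        mods = data.frame(position = 1, delta = 387.194,
            name = "remnant"))
    psm <- matchSpectrum(spA, list(candB, candA), tol)
    expect_equal(psm$sequence, "ACDEK")
    expect_equal(psm$score, 2 * 4)
    # empty peak list scores zero
    spEmpty <- Spectrum("s2", spA$precursorMz, 2,
        data.frame(mz = numeric(0), intensity = numeric(0)))
    psm0 <- matchSpectrum(spEmpty, list(candA), tol)
    expect_equal(psm0$score, 0)
    # nothing passes an impossible precursor filter
    spOff <- Spectrum("s3", spA$precursorMz + 10, 2, spA$peaks)
    expect_null(matchSpectrum(spOff, list(candA), tol))
})

test_that("greedy peak assignment attains the exhaustive matching optimum", {
    set.seed(31)
    for (i in 1:200) {
        theo <- sort(runif(sample(2:6, 1), 100, 400))
        obs <- sort(c(theo[runif(length(theo)) < 0.6] +
            runif(1, -0.5, 0.5), runif(sample(0:4, 1), 100, 400)))
        got <- probescout:::.countMatched(theo, obs, 0.8)
        want <- oracleMatchCount(theo, obs, 0.8)
        expect_identical(got, want)
    }
})

test_that("localization reproduces the closed-form binomial score", {
    # two Cys (positions 2 and 4); the four site-determining ions of
    # placement 2 (b2, b3, y2, y3) all present, none of placement 4
    seqn <- "ACGCK"
    ions2 <- fragmentIons(seqn, data.frame(position = 2, delta = 387.194))
    keep <- ions2$index %in% 2:3
    sp <- Spectrum("s", mz(peptideMass(seqn) + 387.194, 2), 2,
        data.frame(mz = ions2$mz[keep], intensity = 100))
    loc <- localizeSite(sp, seqn, remnantFix, c(2, 4), peakDepth = 10)
    expect_equal(loc$best_site, 2)
    expect_equal(loc$runner_up_site, 4)
    # P(X >= 4; n=4, p=0.1) = 1e-4 vs P(X >= 0) = 1: ascore = 40
    expect_equal(loc$ascore, 40, tolerance = 1e-6)
})

test_that("localization handles the degenerate cases", {
    # single Cys: trivially localized at the sentinel cap
    sp <- Spectrum("s", 500, 2, data.frame(mz = 200, intensity = 1))
    loc1 <- localizeSite(sp, "ACK", remnantFix, 2)
    expect_equal(loc1$ascore, 1000)
    expect_true(is.na(loc1$runner_up_site))
    # no site-determining evidence either way: ascore 0
    spEmpty <- Spectrum("s", 500, 2,
        data.frame(mz = numeric(0), intensity = numeric(0)))
    loc0 <- localizeSite(spEmpty, "ACGCK", remnantFix, c(2, 4))
    expect_equal(loc0$ascore, 0)
    expect_error(localizeSite(sp, "ACK", remnantFix, 1), "not a Cys")
})

test_that("localization is invariant to uniform intensity scaling", {
    set.seed(32)
    cfg <- simConfig()
    for (i in 1:20) {
        pep <- randomCysPeptide(sample(8:16, 1), 2)
        site <- sample(pep$cys, 1)
        sp <- simulateSpectra(data.frame(sequence = pep$sequence,
            mod_position = site), probeRemnant(), cfg,
            seed = 100 + i)[[1]]
        a <- localizeSite(sp, pep$sequence, probeRemnant(), pep$cys)
        sp$peaks$intensity <- sp$peaks$intensity * 1e3
        b <- localizeSite(sp, pep$sequence, probeRemnant(), pep$cys)
        expect_identical(a, b)
    }
})

test_that("target-decoy q-values match hand-computed thresholds", {
    psms <- data.frame(score = c(10, 9, 8, 7),
        is_decoy = c(FALSE, TRUE, FALSE, TRUE),
        protein_id = c("A", "rA", "B", "rB"))
    res <- assignFdr(psms, peptideFdr = 0.5, proteinFdr = 1)
    expect_equal(res$q_value[res$score == 10], 0)
    expect_equal(res$q_value[res$score == 8], 1 / 2)
    # all targets above all decoys: q = 0 everywhere, all retained
    psms2 <- data.frame(score = c(10, 9, 2, 1),
        is_decoy = c(FALSE, FALSE, TRUE, TRUE),
        protein_id = c("A", "B", "rA", "rB"))
    res2 <- assignFdr(psms2)
    expect_true(all(res2$q_value[!res2$is_decoy] == 0))
    expect_true(all(res2$retained[!res2$is_decoy]))
    # no decoys at all: uncalibrated zeros with a warning
    expect_warning(res3 <- assignFdr(psms2[!psms2$is_decoy, ]),
        "uncalibrated")
    expect_true(all(res3$q_value == 0))
    expect_error(assignFdr(psms2[psms2$is_decoy, ]), "no target")
})

test_that("q-values are monotone non-increasing in score", {
    set.seed(33)
    for (i in 1:20) {
        n <- 200
        psms <- data.frame(score = c(rnorm(n, 8, 3), rnorm(n, 5, 3)),
            is_decoy = rep(c(FALSE, TRUE), each = n),
            protein_id = paste0("P", 1:(2 * n)))
        res <- assignFdr(psms)
        ord <- order(-res$score)
        expect_true(all(diff(res$q_value[ord]) >= -1e-12))
    }
})

test_that("realized FDP of the peptide-level filter is controlled", {
    # planted true peptides score high; null targets and decoys share
    # the same null score distribution
    set.seed(34)
    falseDisc <- 0L
    disc <- 0L
    for (i in 1:200) {
        nTrue <- 40L; nNull <- 120L
        scores <- c(rnorm(nTrue, 20, 2), rnorm(nNull, 5, 2),
            rnorm(nNull, 5, 2))
        isDecoy <- rep(c(FALSE, TRUE), c(nTrue + nNull, nNull))
        psms <- data.frame(score = scores, is_decoy = isDecoy,
            protein_id = paste0("P", seq_along(scores)))
        res <- assignFdr(psms, peptideFdr = 0.05, proteinFdr = 1)
        kept <- which(res$retained)
        disc <- disc + length(kept)
        falseDisc <- falseDisc + sum(kept > nTrue)
    }
    expect_lte(falseDisc / disc, 0.10)
    expect_gt(disc, 200 * 40 * 0.9)
})

test_that("searchSpectra identifies planted peptides with localization", {
    set.seed(35)
    cfg <- simConfig(nProteins = 12L)
    sim <- simulateProteome(cfg, seed = 41)
    expt <- simulateLabelingExperiment(sim, config = cfg, seed = 42)
    psms <- suppressWarnings(searchSpectra(expt$spectra, sim$proteome,
        standardSchemes()[["trypsin_lysC_gluC"]]))
    expect_true(all(c("site", "ascore", "q_value", "retained") %in%
        names(psms)))
    # every spectrum yields at most one PSM
    expect_lte(max(table(psms$spectrum_id)), 1L)
    truthKey <- paste(expt$evidence$protein_id, expt$evidence$site)
    psmKey <- paste(psms$protein_id, psms$site)
    m <- match(psms$spectrum_id, expt$evidence$spectrum_id)
    expect_gt(mean(psmKey == truthKey[m]), 0.9)
})
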