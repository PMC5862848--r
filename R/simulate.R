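# Synthetic-data generator: proteomes with DUB-like active-site windows,
# probe-labeling events, fragment spectra, and overdispersed feature
# counts, all with ground truth for recovery testing.

# residue alphabet used for random sequences; roughly uniform composition
# is adequate for digestion and search behaviour
.AA <- names(.RESIDUES)

#' Simulation configuration
#'
#' Defaults encode the study design being emulated: a probe condition
#' against a negative-control condition in three biological replicates,
#' overdispersed negative-binomial feature counts (mean 50, dispersion
#' 0.2), an eightfold (log2 effect 3) enrichment on true targets, and
#' spectra retaining each fragment ion with probability 0.7 plus five
#' noise peaks.
#'
#' @param nProteins proteome size.
#' @param lengthRange protein length bounds (residues).
#' @param fracDub fraction of proteins given a DUB-like catalytic-Cys
#'   window.
#' @param windowLength length of the K/R-free, Glu-containing active-site
#'   window around the catalytic Cys (long tryptic peptides by
#'   construction).
#' @param reactiveNonCatalyticProb probability that any non-catalytic Cys
#'   is probe-reactive.
#' @param labelProbProbe per-replicate probability that a reactive site is
#'   labeled in the probe condition.
#' @param labelProbControl same for the control condition (the control
#'   probe does not covalently label targets; default 0).
#' @param nbMu,nbDispersion negative-binomial mean and dispersion of
#'   background feature counts.
#' @param log2Effect planted log2 enrichment on true targets.
#' @param fracEnriched fraction of proteins truly enriched in
#'   counts-only simulations.
#' @param nReplicates biological replicates per condition.
#' @param peakRetention probability a theoretical fragment ion appears in
#'   the spectrum.
#' @param noisePeaks number of uniform noise peaks added per spectrum.
#' @param precursorJitterPpm precursor m/z jitter bound (ppm).
#' @param charge precursor charge assigned to simulated spectra.
#' @return list of simulation parameters.
#' @export
simConfig <- function(nProteins = 60L, lengthRange = c(120L, 300L),
        fracDub = 0.25, windowLength = 50L,
        reactiveNonCatalyticProb = 0.1,
        labelProbProbe = 0.9, labelProbControl = 0,
        nbMu = 50, nbDispersion = 0.2, log2Effect = 3,
        fracEnriched = 0.1, nReplicates = 3L,
        peakRetention = 0.7, noisePeaks = 5L, precursorJitterPpm = 3,
        charge = 2L) {
    stopifnot(nProteins >= 1L, lengthRange[1] <= lengthRange[2],
        fracDub >= 0, fracDub <= 1, nbMu > 0, nbDispersion > 0,
        peakRetention >= 0, peakRetention <= 1,
        labelProbProbe >= 0, labelProbProbe <= 1)
    if (lengthRange[1] < windowLength + 10L)
        stop("proteins too short for the active-site window")
    as.list(environment())
}

# a K/R-free window containing the catalytic Cys flanked by Glu residues,
# so the trypsin-only peptide spanning the site is long while Glu-C
# cleavage trims it
.activeSiteWindow <- function(len) {
    pool <- setdiff(.AA, c("K", "R", "C", "E"))
    w <- sample(pool, len, replace = TRUE)
    mid <- ceiling(len / 2)
    w[mid] <- "C"
    eUp <- max(1L, mid - 8L)
    eDown <- min(len, mid + 8L)
    w[eUp] <- "E"
    w[eDown] <- "E"
    w
}

#' Simulate a proteome with annotated reactive sites
#'
#' Random sequences over the 20 canonical residues; a `fracDub` fraction
#' receives a DUB-like active-site window: a K/R-sparse stretch holding
#' the catalytic Cys with nearby Glu residues, so that the tryptic
#' peptide spanning the site is long but a second Glu-C digestion trims
#' it into the detectable range. Ground truth records the class, the
#' catalytic site, and all probe-reactive Cys sites.
#'
#' @param config a [simConfig()].
#' @param seed integer seed; the generator is deterministic given the
#'   seed.
#' @return list with `proteome` (named character), `annotation`
#'   (data.frame: protein_id, class, catalytic_sites) and `truth`
#'   (data.frame: protein_id, class, catalytic_site, reactive_sites
#'   comma-separated 1-based, enriched).
#' @export
simulateProteome <- function(config = simConfig(), seed = 1L) {
    set.seed(seed)
    n <- config$nProteins
    nDub <- round(n * config$fracDub)
    isDub <- seq_len(n) <= nDub
    ids <- sprintf("P%03d", seq_len(n))
    proteome <- character(n)
    catalytic <- rep(NA_integer_, n)
    reactive <- vector("list", n)
    for (i in seq_len(n)) {
        len <- sample(config$lengthRange[1]:config$lengthRange[2], 1L)
        s <- sample(.AA, len, replace = TRUE)
        if (isDub[i]) {
            wl <- config$windowLength
            at <- sample(seq.int(10L, len - wl - 10L), 1L)
            s[at:(at + wl - 1L)] <- .activeSiteWindow(wl)
            catalytic[i] <- at + ceiling(wl / 2) - 1L
        }
        proteome[i] <- paste(s, collapse = "")
        cys <- which(s == "C")
        others <- setdiff(cys, catalytic[i])
        hot <- others[stats::runif(length(others)) <
            config$reactiveNonCatalyticProb]
        reactive[[i]] <- sort(unique(c(catalytic[i][!is.na(catalytic[i])],
            hot)))
    }
    names(proteome) <- ids
    annotation <- data.frame(protein_id = ids,
        class = ifelse(isDub, "DUB", "Other"),
        catalytic_sites = ifelse(is.na(catalytic), "",
            as.character(catalytic)),
        stringsAsFactors = FALSE)
    truth <- data.frame(protein_id = ids,
        class = annotation$class,
        catalytic_site = catalytic,
        reactive_sites = vapply(reactive, paste, character(1),
            collapse = ","),
        enriched = isDub,
        stringsAsFactors = FALSE)
    list(proteome = proteome, annotation = annotation, truth = truth)
}

#' Simulate a feature-count matrix
#'
#' Counts are negative binomial with dispersion `nbDispersion`; enriched
#' proteins have their probe-condition mean multiplied by
#' `2^log2Effect`. The design is `nReplicates` probe vs `nReplicates`
#' control samples.
#'
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @param nProteins number of proteins (defaults to `config$nProteins`).
#' @param enriched logical vector of true enrichment status; defaults to
#'   a random `fracEnriched` fraction.
#' @return `SummarizedExperiment` of counts with `condition`/`replicate`
#'   colData; `rowData` holds the `enriched` truth.
#' @export
simulateCounts <- function(config = simConfig(), seed = 1L,
        nProteins = config$nProteins, enriched = NULL) {
    set.seed(seed)
    if (is.null(enriched))
        enriched <- stats::runif(nProteins) < config$fracEnriched
    stopifnot(length(enriched) == nProteins)
    nr <- config$nReplicates
    condition <- rep(c("control", "probe"), each = nr)
    replicate <- rep(paste0("R", seq_len(nr)), times = 2L)
    size <- 1 / config$nbDispersion
    mu <- matrix(config$nbMu, nProteins, 2L * nr)
    mu[enriched, condition == "probe"] <-
        config$nbMu * 2^config$log2Effect
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
        nProteins, 2L * nr)
    rownames(counts) <- sprintf("P%03d", seq_len(nProteins))
    colnames(counts) <- paste0(condition, "_", replicate)
    se <- featureCountMatrix(counts, condition, replicate)
    SummarizedExperiment::rowData(se)$enriched <- enriched
    se
}

#' Simulate fragment spectra of remnant-modified peptides
#'
#' Each input peptide yields one spectrum: its singly-charged b/y ions
#' (remnant applied at the labeled position) are retained independently
#' with probability `peakRetention`; `noisePeaks` uniform noise peaks are
#' added; the precursor m/z is jittered within the stated ppm bound.
#'
#' @param peptides data.frame with columns `sequence`, `mod_position`
#'   (1-based within the peptide), plus optional bookkeeping columns
#'   (`protein_id`, `start`, `sample_id`, `replicate`, `condition`)
#'   copied onto the spectra.
#' @param remnant the probe-remnant [Modification-class].
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @return list of [Spectrum()] objects.
#' @export
simulateSpectra <- function(peptides, remnant, config = simConfig(),
        seed = 1L) {
    set.seed(seed)
    out <- vector("list", nrow(peptides))
    for (i in seq_len(nrow(peptides))) {
        seqi <- peptides$sequence[i]
        mods <- data.frame(position = peptides$mod_position[i],
            delta = remnant@deltaMass, name = remnant@name)
        ions <- fragmentIons(seqi, mods, maxCharge = 1L)
        keep <- stats::runif(nrow(ions)) < config$peakRetention
        realPeaks <- data.frame(mz = ions$mz[keep],
            intensity = stats::runif(sum(keep), 200, 1000))
        nNoise <- config$noisePeaks
        noise <- data.frame(
            mz = stats::runif(nNoise, 100, max(ions$mz) + 100),
            intensity = stats::runif(nNoise, 10, 400))
        peaks <- rbind(realPeaks, noise)
        z <- config$charge
        theo <- mz(peptideMass(seqi, mods), z)
        jit <- stats::runif(1, -config$precursorJitterPpm,
            config$precursorJitterPpm)
        out[[i]] <- Spectrum(
            id = if ("spectrum_id" %in% names(peptides))
                peptides$spectrum_id[i] else sprintf("sim%05d", i),
            precursorMz = theo * (1 + jit * 1e-6),
            charge = z, peaks = peaks,
            sample_id = if ("sample_id" %in% names(peptides))
                peptides$sample_id[i] else NA_character_,
            replicate = if ("replicate" %in% names(peptides))
                peptides$replicate[i] else NA_character_,
            condition = if ("condition" %in% names(peptides))
                peptides$condition[i] else NA_character_)
    }
    out
}

#' The three standard digestion conditions
#'
#' Trypsin/Lys-C alone, trypsin/Lys-C followed by Glu-C, and
#' trypsin/Lys-C followed by chymotrypsin, each releasing labeled
#' peptides with the given remnant.
#'
#' @param remnant probe-remnant [Modification-class].
#' @return named list of [DigestionScheme-class] objects.
#' @export
standardSchemes <- function(remnant = probeRemnant()) {
    t1 <- list(getEnzyme("trypsin"), getEnzyme("lysC"))
    list(
        trypsin_lysC = DigestionScheme(t1, remnant),
        trypsin_lysC_gluC = DigestionScheme(t1, remnant,
            step2Enzyme = getEnzyme("gluC")),
        trypsin_lysC_chymotrypsin = DigestionScheme(t1, remnant,
            step2Enzyme = getEnzyme("chymotrypsin")))
}

#' Simulate a full labeling experiment
#'
#' For each biological replicate and digestion condition, reactive sites
#' are labeled with the per-condition probability, the protein is pushed
#' through the sequential on-bead digestion simulator, and each labeled
#' cleaved-fraction peptide inside the detectability window yields one
#' simulated spectrum.
#'
#' @param sim result of [simulateProteome()].
#' @param schemes named list of [DigestionScheme-class]; defaults to the
#'   trypsin/Lys-C + Glu-C sequential scheme only.
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @param window a [detectabilityWindow()].
#' @return list with `spectra` (list of [Spectrum()]), `evidence`
#'   (data.frame of planted peptides) and `plantedSites` (data.frame
#'   protein_id, site [1-based], replicates it was labeled in).
#' @export
simulateLabelingExperiment <- function(sim,
        schemes = standardSchemes()["trypsin_lysC_gluC"],
        config = simConfig(), seed = 1L,
        window = detectabilityWindow()) {
    set.seed(seed)
    reactive <- lapply(strsplit(sim$truth$reactive_sites, ","),
        function(x) as.integer(x[nzchar(x)]))
    names(reactive) <- sim$truth$protein_id
    peptides <- list()
    for (r in seq_len(config$nReplicates)) {
        repId <- paste0("R", r)
        for (pid in names(reactive)) {
            sites <- reactive[[pid]]
            if (!length(sites)) next
            labeled <- sites[stats::runif(length(sites)) <
                config$labelProbProbe]
            if (!length(labeled)) next
            for (sn in names(schemes)) {
                sch <- schemes[[sn]]
                fr <- sequentialOnBeadDigest(sim$proteome[[pid]],
                    labeled - 1L, sch)
                cl <- fr$cleaved
                for (k in seq_len(nrow(cl))) {
                    lab <- cl$labeled[[k]]
                    pepLen <- nchar(cl$sequence[k])
                    massK <- peptideMass(cl$sequence[k]) +
                        length(lab) * sch@remnant@deltaMass
                    if (pepLen < window$minLength ||
                        pepLen > window$maxLength ||
                        massK < window$minMass || massK > window$maxMass)
                        next
                    # one remnant per peptide: spectra are generated for
                    # the first labeled Cys of multiply-labeled peptides
                    peptides[[length(peptides) + 1L]] <- data.frame(
                        protein_id = pid, start = cl$start[k],
                        sequence = cl$sequence[k],
                        mod_position = lab[1L] - cl$start[k] + 1L,
                        site = lab[1L] + 1L,
                        replicate = repId, condition = sn,
                        sample_id = paste0("probe_", repId),
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    if (!length(peptides)) stop("no labeled peptides generated")
    evidence <- do.call(rbind, peptides)
    evidence$spectrum_id <- sprintf("sp%05d", seq_len(nrow(evidence)))
    remnant <- schemes[[1L]]@remnant
    spectra <- simulateSpectra(evidence, remnant, config,
        seed = seed + 1L)
    plantKey <- unique(evidence[, c("protein_id", "site")])
    list(spectra = spectra, evidence = evidence,
        plantedSites = plantKey)
}
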