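# Spectrum matching, probe-site localization and two-tier target-decoy FDR.

#' Construct a fragment spectrum
#'
#' Lightweight container for one MS/MS spectrum. Peaks are kept sorted by
#' m/z.
#'
#' @param id spectrum identifier.
#' @param precursorMz precursor m/z.
#' @param charge precursor charge (>= 1).
#' @param peaks data.frame with columns `mz` and `intensity`.
#' @param sample_id,replicate,condition acquisition metadata carried
#'   through to PSMs.
#' @return A list of class `"Spectrum"`.
#' @export
Spectrum <- function(id, precursorMz, charge, peaks,
        sample_id = NA_character_, replicate = NA_character_,
        condition = NA_character_) {
    stopifnot(charge >= 1L, is.data.frame(peaks),
        all(c("mz", "intensity") %in% names(peaks)))
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    structure(list(id = id, precursorMz = precursorMz,
        charge = as.integer(charge), peaks = peaks,
        sample_id = sample_id, replicate = replicate,
        condition = condition), class = "Spectrum")
}

#' Theoretical b/y fragment ions
#'
#' Enumerates the singly- to `maxCharge`-charged b and y ions of a peptide,
#' applying modification deltas to the fragments that contain the modified
#' residue. For a length-n peptide there are 2(n-1) fragment species per
#' charge state, and neutral(b_i) + neutral(y_{n-i}) equals the peptide's
#' neutral mass.
#'
#' @param sequence peptide sequence (length >= 2).
#' @param mods `data.frame(position, delta)` of modifications (1-based
#'   positions within the peptide), or NULL.
#' @param maxCharge maximum fragment charge state.
#' @return data.frame with columns `type` ("b"/"y"), `index`, `charge`,
#'   `neutral`, `mz`.
#' @examples
#' fragmentIons("ACK", mods = data.frame(position = 2, delta = 387.194))
#' @export
fragmentIons <- function(sequence, mods = NULL, maxCharge = 1L) {
    n <- nchar(sequence)
    if (n < 2L) stop("peptide must have length >= 2")
    res <- strsplit(sequence, "")[[1]]
    deltas <- numeric(n)
    mf <- .modFrame(mods)
    if (nrow(mf)) {
        stopifnot(all(mf$position >= 1L), all(mf$position <= n))
        deltas[mf$position] <- deltas[mf$position] + mf$delta
    }
    rm <- .RESIDUES[res] + deltas
    bNeutral <- cumsum(rm)[-n]
    yNeutral <- cumsum(rev(rm))[-n] + .WATER
    base <- rbind(
        data.frame(type = "b", index = seq_len(n - 1L),
            neutral = bNeutral),
        data.frame(type = "y", index = seq_len(n - 1L),
            neutral = yNeutral))
    out <- do.call(rbind, lapply(seq_len(maxCharge), function(z) {
        cbind(base, charge = z, mz = mz(base$neutral, z))
    }))
    rownames(out) <- NULL
    out[, c("type", "index", "charge", "neutral", "mz")]
}

# maximum number of theoretical ions matchable to observed peaks within
# +/- tol, each peak usable once. Two-pointer greedy over sorted lists:
# matching each theoretical ion to the smallest unused peak in its window
# attains the maximum for interval-structured bipartite graphs.
.countMatched <- function(theoMz, obsMz, tol) {
    theoMz <- sort(theoMz)
    obsMz <- sort(obsMz)
    nT <- length(theoMz); nO <- length(obsMz)
    cnt <- 0L; j <- 1L
    for (i in seq_len(nT)) {
        while (j <= nO && obsMz[j] < theoMz[i] - tol) j <- j + 1L
        if (j > nO) break
        if (obsMz[j] <= theoMz[i] + tol) {
            cnt <- cnt + 1L
            j <- j + 1L
        }
    }
    cnt
}

#' Match a spectrum against candidate peptides
#'
#' Scores each candidate by the number of theoretical b/y ions matched to
#' observed peaks within the fragment tolerance (each observed peak usable
#' once) and returns the best candidate. Candidates failing the precursor
#' ppm filter are dropped first. Ties are broken deterministically: fewer
#' modifications, then lexicographically smaller sequence.
#'
#' @param spectrum a [Spectrum()].
#' @param candidates list of candidates, each a list with `sequence`,
#'   `mods` (`data.frame(position, delta, name)` or NULL) and optional
#'   bookkeeping fields (`protein_id`, `start`, `end`, `is_decoy`).
#' @param tol a [matchTolerance()].
#' @param maxFragmentCharge fragment charges enumerated (default 1).
#' @return One-row data.frame PSM (spectrum id, candidate fields, `score`),
#'   or NULL when no candidate passes the precursor filter.
#' @export
matchSpectrum <- function(spectrum, candidates, tol = matchTolerance(),
        maxFragmentCharge = 1L) {
    if (!length(candidates)) return(NULL)
    z <- spectrum$charge
    keep <- vapply(candidates, function(cand) {
        m <- peptideMass(cand$sequence, cand$mods)
        abs(ppmError(spectrum$precursorMz, mz(m, z))) <= tol$precursorPpm
    }, logical(1))
    candidates <- candidates[keep]
    if (!length(candidates)) return(NULL)
    scores <- vapply(candidates, function(cand) {
        ions <- fragmentIons(cand$sequence, cand$mods, maxFragmentCharge)
        .countMatched(ions$mz, spectrum$peaks$mz, tol$fragmentDa)
    }, integer(1))
    nmods <- vapply(candidates, function(cand)
        nrow(.modFrame(cand$mods)), integer(1))
    seqs <- vapply(candidates, `[[`, character(1), "sequence")
    best <- order(-scores, nmods, seqs)[1L]
    cand <- candidates[[best]]
    mf <- .modFrame(cand$mods)
    data.frame(
        spectrum_id = spectrum$id,
        protein_id = if (is.null(cand$protein_id)) NA_character_ else
            cand$protein_id,
        start = if (is.null(cand$start)) NA_integer_ else cand$start,
        end = if (is.null(cand$end)) NA_integer_ else cand$end,
        sequence = cand$sequence,
        mods = if (nrow(mf)) paste(sprintf("%d:%s", mf$position,
            ifelse(is.na(mf$name), sprintf("%+.4f", mf$delta), mf$name)),
            collapse = ";") else "",
        charge = z,
        score = scores[best],
        is_decoy = isTRUE(cand$is_decoy),
        sample_id = spectrum$sample_id,
        replicate = spectrum$replicate,
        condition = spectrum$condition,
        stringsAsFactors = FALSE)
}

# retain the top `depth` peaks by intensity per 100-m/z window
.filterPeakDepth <- function(peaks, depth) {
    if (!nrow(peaks)) return(peaks)
    win <- floor(peaks$mz / 100)
    keep <- unlist(lapply(split(seq_len(nrow(peaks)), win), function(ix) {
        ix[order(-peaks$intensity[ix])][seq_len(min(depth, length(ix)))]
    }), use.names = FALSE)
    peaks[sort(keep), , drop = FALSE]
}

#' Localize the probe-labeled Cys within a peptide
#'
#' Binomial localization score in the Ascore style. For each candidate
#' placement of the remnant, the site-determining ions (theoretical ions
#' whose m/z differs from some alternative placement) are matched against
#' the spectrum filtered to the top `peakDepth` peaks per 100 m/z. The
#' per-placement probability of matching at least k of n determining ions
#' by chance is the binomial survival function with p = peakDepth/100;
#' each placement scores -10*log10(P), and the localization score is the
#' difference between the best and runner-up placements. A peptide with a
#' single candidate Cys is trivially localized (score capped at 1000).
#'
#' The score is invariant to uniform intensity scaling, since the peak
#' filter depends only on intensity ranks.
#'
#' @param spectrum a [Spectrum()].
#' @param sequence peptide sequence.
#' @param remnant the probe-remnant [Modification-class].
#' @param candidateSites 1-based Cys positions within the peptide.
#' @param peakDepth retained peaks per 100 m/z (default 10; binomial
#'   p = peakDepth/100).
#' @param fragmentDa fragment match tolerance (Da).
#' @param baseMods modifications common to all placements
#'   (`data.frame(position, delta, name)`), e.g. carbamidomethyl on
#'   unlabeled Cys.
#' @return list with `best_site`, `runner_up_site` (NA when unambiguous),
#'   `ascore`.
#' @export
localizeSite <- function(spectrum, sequence, remnant, candidateSites,
        peakDepth = 10L, fragmentDa = 0.8, baseMods = NULL) {
    res <- strsplit(sequence, "")[[1]]
    candidateSites <- as.integer(candidateSites)
    if (any(res[candidateSites] != "C"))
        stop("candidate site is not a Cys")
    if (length(candidateSites) == 1L)
        return(list(best_site = candidateSites, runner_up_site = NA_integer_,
            ascore = 1000))
    peaks <- .filterPeakDepth(spectrum$peaks, peakDepth)
    placements <- lapply(candidateSites, function(s) {
        mods <- rbind(.modFrame(baseMods),
            data.frame(position = s, delta = remnant@deltaMass,
                name = remnant@name))
        round(fragmentIons(sequence, mods)$mz, 4)
    })
    shared <- Reduce(intersect, placements)
    p <- peakDepth / 100
    scores <- vapply(seq_along(candidateSites), function(i) {
        det <- setdiff(placements[[i]], shared)
        n <- length(det)
        if (!n) return(0)
        k <- .countMatched(det, peaks$mz, fragmentDa)
        P <- stats::pbinom(k - 1L, n, p, lower.tail = FALSE)
        min(-10 * log10(max(P, 1e-100)), 1000)
    }, numeric(1))
    ord <- order(-scores, candidateSites)
    list(best_site = candidateSites[ord[1L]],
        runner_up_site = candidateSites[ord[2L]],
        ascore = min(scores[ord[1L]] - scores[ord[2L]], 1000))
}

#' Two-tier target-decoy false discovery rate filter
#'
#' Estimates peptide-level q-values from the decoy competition
#' (q at score s = decoys >= s over targets >= s, monotonized to be
#' non-increasing in score), retains PSMs at `peptideFdr`, then computes
#' protein-level q-values over the best retained peptide score per protein
#' and retains proteins at `proteinFdr`. Defaults are 5% peptide / 2%
#' protein.
#'
#' @param psms data.frame with at least `score`, `is_decoy`, `protein_id`.
#' @param peptideFdr peptide-level threshold (default 0.05).
#' @param proteinFdr protein-level threshold (default 0.02).
#' @return `psms` with added columns `q_value` (peptide tier), `protein_q`,
#'   and logical `retained` (target PSMs passing both tiers).
#' @export
assignFdr <- function(psms, peptideFdr = 0.05, proteinFdr = 0.02) {
    stopifnot(all(c("score", "is_decoy", "protein_id") %in% names(psms)))
    if (!any(!psms$is_decoy)) stop("no target PSMs")
    noDecoys <- !any(psms$is_decoy)
    if (noDecoys)
        warning("no decoy PSMs: q-values are all 0 (uncalibrated)")
    psms$q_value <- .tdQvalues(psms$score, psms$is_decoy)
    pepPass <- psms$q_value <= peptideFdr
    prot <- psms[pepPass, , drop = FALSE]
    if (nrow(prot)) {
        agg <- stats::aggregate(score ~ protein_id + is_decoy, data = prot,
            FUN = max)
        agg$protein_q <- .tdQvalues(agg$score, agg$is_decoy)
        protPass <- agg$protein_id[!agg$is_decoy &
            agg$protein_q <= proteinFdr]
        psms$protein_q <- agg$protein_q[match(psms$protein_id,
            agg$protein_id)]
    } else {
        protPass <- character(0)
        psms$protein_q <- NA_real_
    }
    psms$retained <- !psms$is_decoy & pepPass &
        psms$protein_id %in% protPass
    psms
}

# target-decoy q-values, monotone non-increasing in score
.tdQvalues <- function(score, isDecoy) {
    if (!any(isDecoy)) return(rep(0, length(score)))
    thr <- sort(unique(score), decreasing = TRUE)
    nD <- vapply(thr, function(s) sum(isDecoy & score >= s), integer(1))
    nT <- vapply(thr, function(s) sum(!isDecoy & score >= s), integer(1))
    fdr <- ifelse(nT > 0, nD / nT, 0)
    q <- rev(cummin(rev(fdr)))
    q[match(score, thr)]
}

#' Reverse a proteome to build decoy sequences
#'
#' Whole-protein sequence reversal keeps the length and composition
#' distribution of the target database.
#'
#' @param proteome named character vector or `AAStringSet`.
#' @param prefix id prefix marking decoys.
#' @return Named character vector of reversed sequences.
#' @export
reverseProteome <- function(proteome, prefix = "rev_") {
    proteome <- .asSequences(proteome)
    out <- vapply(proteome, function(s)
        paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1))
    names(out) <- paste0(prefix, names(proteome))
    out
}

# enumerate remnant-modified search candidates for one protein:
# digest with the scheme's enzymes (union when a second protease is used),
# keep Cys-containing peptides, one candidate per possible remnant site
.remnantCandidates <- function(sequence, proteinId, scheme, isDecoy) {
    enz <- scheme@step1Enzymes
    mm <- scheme@step1MaxMissed
    if (!is.null(scheme@step2Enzyme)) {
        enz <- c(enz, list(scheme@step2Enzyme))
        mm <- scheme@step2MaxMissed
    }
    pep <- digest(sequence, enz, maxMissed = mm)
    pep <- pep[grepl("C", pep$sequence, fixed = TRUE) &
        nchar(pep$sequence) >= 2L, , drop = FALSE]
    if (!nrow(pep)) return(list())
    out <- list()
    for (i in seq_len(nrow(pep))) {
        cpos <- which(strsplit(pep$sequence[i], "")[[1]] == "C")
        for (s in cpos) {
            out[[length(out) + 1L]] <- list(
                protein_id = proteinId,
                start = pep$start[i], end = pep$end[i],
                sequence = pep$sequence[i],
                mods = data.frame(position = s,
                    delta = scheme@remnant@deltaMass,
                    name = scheme@remnant@name),
                site0 = pep$start[i] + s - 1L,
                is_decoy = isDecoy)
        }
    }
    out
}

#' Search spectra for remnant-modified peptides
#'
#' Runs the full identification stage: enumerates remnant-modified
#' candidate peptides from the target proteome and its reversed decoy,
#' matches every spectrum to its best candidate, localizes the labeled Cys
#' for peptides with more than one Cys, and applies the two-tier
#' target-decoy FDR filter.
#'
#' @param spectra list of [Spectrum()] objects.
#' @param proteome named character vector or `AAStringSet`.
#' @param scheme a [DigestionScheme-class].
#' @param tol a [matchTolerance()].
#' @param peptideFdr,proteinFdr FDR tier thresholds (5% / 2% defaults).
#' @param minScore minimum matched-ion score to keep a PSM before FDR
#'   (post-hoc ion-score gate; default 0 = off).
#' @param peakDepth localization peak depth per 100 m/z.
#' @param withDecoys set FALSE to search targets only (uncalibrated).
#' @return data.frame of PSMs with localization (`site`, 1-based within
#'   the protein; `ascore`) and FDR columns (`q_value`, `retained`).
#' @export
searchSpectra <- function(spectra, proteome, scheme,
        tol = matchTolerance(), peptideFdr = 0.05, proteinFdr = 0.02,
        minScore = 0L, peakDepth = 10L, withDecoys = TRUE) {
    proteome <- .asSequences(proteome)
    cands <- list()
    for (pid in names(proteome))
        cands <- c(cands, .remnantCandidates(proteome[[pid]], pid,
            scheme, FALSE))
    if (withDecoys) {
        dec <- reverseProteome(proteome)
        for (pid in names(dec))
            cands <- c(cands, .remnantCandidates(dec[[pid]], pid,
                scheme, TRUE))
    }
    if (!length(cands)) stop("no Cys-containing candidate peptides")
    candMass <- vapply(cands, function(cand)
        peptideMass(cand$sequence, cand$mods), numeric(1))
    psms <- list()
    for (sp in spectra) {
        theoMz <- (candMass + sp$charge * .PROTON) / sp$charge
        hit <- which(abs(1e6 * (sp$precursorMz - theoMz) / theoMz) <=
            tol$precursorPpm)
        if (!length(hit)) next
        psm <- matchSpectrum(sp, cands[hit], tol)
        if (is.null(psm) || psm$score < minScore) next
        cand <- cands[hit][[which(vapply(cands[hit], function(cc)
            identical(cc$sequence, psm$sequence) &&
            identical(cc$protein_id, psm$protein_id) &&
            cc$start == psm$start, logical(1)))[1L]]]
        cys <- which(strsplit(psm$sequence, "")[[1]] == "C")
        loc <- localizeSite(sp, psm$sequence, scheme@remnant, cys,
            peakDepth = peakDepth, fragmentDa = tol$fragmentDa)
        psm$site <- psm$start + loc$best_site  # 1-based in protein
        psm$ascore <- loc$ascore
        psms[[length(psms) + 1L]] <- psm
    }
    if (!length(psms)) stop("no PSMs found")
    psms <- do.call(rbind, psms)
    assignFdr(psms, peptideFdr, proteinFdr)
}
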