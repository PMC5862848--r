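# In-silico proteolysis and the sequential on-bead digestion workflow.
# Internal coordinates are 0-based half-open; user-facing residue numbers
# are 1-based.

.ENZYMES <- list(
    trypsin = list(cleaveAfter = c("K", "R"), blockedByNext = "P"),
    lysC = list(cleaveAfter = "K", blockedByNext = character(0)),
    chymotrypsin = list(cleaveAfter = c("F", "W", "Y", "L"),
        blockedByNext = "P"),
    gluC = list(cleaveAfter = "E", blockedByNext = character(0))
)

#' Named protease with its cleavage rule
#'
#' Built-in rules: trypsin cleaves after K/R except before P; Lys-C after K
#' (not blocked); chymotrypsin after F/W/Y/L except before P; Glu-C after E
#' (ammonium bicarbonate buffer specificity; set `gluCAspartate = TRUE` for
#' the E+D variant).
#'
#' @param name one of `"trypsin"`, `"lysC"`, `"chymotrypsin"`, `"gluC"`.
#' @param gluCAspartate if TRUE, Glu-C also cleaves after Asp.
#' @return An [Enzyme-class].
#' @examples
#' getEnzyme("trypsin")
#' @export
getEnzyme <- function(name = c("trypsin", "lysC", "chymotrypsin", "gluC"),
        gluCAspartate = FALSE) {
    name <- match.arg(name)
    rule <- .ENZYMES[[name]]
    ca <- rule$cleaveAfter
    if (name == "gluC" && gluCAspartate) ca <- c(ca, "D")
    Enzyme(name, ca, rule$blockedByNext)
}

# 0-based cut positions: cut after 1-based residue i => boundary i
.cutSites <- function(residues, enzymes) {
    n <- length(residues)
    if (n < 2L) return(integer(0))
    cuts <- logical(n - 1L)
    for (e in enzymes) {
        hit <- residues[-n] %in% e@cleaveAfter &
            !(residues[-1L] %in% e@blockedByNext)
        cuts <- cuts | hit
    }
    which(cuts)
}

#' Digest a sequence in silico
#'
#' Applies the joint cleavage rule of one or more proteases and returns all
#' peptides spanning at most `maxMissed` internal (missed) cleavage sites.
#' With `maxMissed = 0` the peptides tile the sequence exactly once.
#'
#' @param sequence protein sequence (single string).
#' @param enzymes an [Enzyme-class] or list of them, applied jointly.
#' @param maxMissed maximum number of missed cleavages (>= 0).
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `sequence`, `missed_cleavages`, ordered by start then end.
#' @examples
#' digest("AKAR", getEnzyme("trypsin"), maxMissed = 1)
#' @export
digest <- function(sequence, enzymes, maxMissed = 0L) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (!nzchar(sequence)) stop("empty sequence")
    stopifnot(maxMissed >= 0L)
    if (is(enzymes, "Enzyme")) enzymes <- list(enzymes)
    res <- strsplit(sequence, "")[[1]]
    bounds <- c(0L, .cutSites(res, enzymes), length(res))
    nb <- length(bounds)
    out <- vector("list", nb - 1L)
    for (i in seq_len(nb - 1L)) {
        jmax <- min(nb, i + 1L + maxMissed)
        j <- seq.int(i + 1L, jmax)
        out[[i]] <- data.frame(start = bounds[i], end = bounds[j],
            missed_cleavages = j - i - 1L)
    }
    pep <- do.call(rbind, out)
    pep <- pep[order(pep$start, pep$end), , drop = FALSE]
    pep$sequence <- substring(sequence, pep$start + 1L, pep$end)
    rownames(pep) <- NULL
    pep[, c("start", "end", "sequence", "missed_cleavages")]
}

#' Simulate the sequential on-bead digestion of a labeled protein
#'
#' Step 1 digests the full protein to completion; fully cleaved peptides
#' that carry no labeled Cys are released into the on-bead digestion
#' fraction (used for protein-level identification), while label-bearing
#' peptides stay bead-bound via the biotin tag. If the scheme has a second
#' protease, the retained peptides are re-digested: label-free sub-peptides
#' are washed away, label-bearing ones remain. Linker cleavage finally
#' releases the retained peptides into the cleaved fraction, with the
#' probe-remnant modification attached to each labeled Cys.
#'
#' The physical digest is modelled as complete cleavage, so the three
#' fractions partition the protein's residues exactly; the scheme's
#' missed-cleavage limits apply to in-silico search-candidate enumeration,
#' not to this simulation.
#'
#' @param sequence protein sequence.
#' @param labeledPositions 0-based indices of probe-labeled Cys residues.
#' @param scheme a [DigestionScheme-class].
#' @return list with data.frames `onbead`, `washed`, `cleaved` (columns
#'   `start`, `end`, `sequence`; `cleaved` additionally has a list-column
#'   `labeled` of 0-based labeled positions and the remnant name/delta).
#' @examples
#' sch <- DigestionScheme(getEnzyme("trypsin"), probeRemnant())
#' sequentialOnBeadDigest("AKCAR", labeledPositions = 2L, scheme = sch)
#' @export
sequentialOnBeadDigest <- function(sequence, labeledPositions, scheme) {
    stopifnot(is(scheme, "DigestionScheme"))
    labeledPositions <- as.integer(labeledPositions)
    res <- strsplit(sequence, "")[[1]]
    if (length(labeledPositions)) {
        if (any(labeledPositions < 0L |
                labeledPositions >= length(res)))
            stop("labeled position out of range")
        if (any(res[labeledPositions + 1L] != "C"))
            stop("labeled position is not a Cys")
    }
    emptyFrac <- function() data.frame(start = integer(0),
        end = integer(0), sequence = character(0))
    covers <- function(pep) {
        vapply(seq_len(nrow(pep)), function(i) any(
            labeledPositions >= pep$start[i] &
            labeledPositions < pep$end[i]), logical(1))
    }
    s1 <- digest(sequence, scheme@step1Enzymes, maxMissed = 0L)
    lab1 <- if (nrow(s1)) covers(s1) else logical(0)
    onbead <- s1[!lab1, c("start", "end", "sequence"), drop = FALSE]
    retained <- s1[lab1, , drop = FALSE]
    washed <- emptyFrac()
    if (!is.null(scheme@step2Enzyme) && nrow(retained)) {
        pieces <- lapply(seq_len(nrow(retained)), function(i) {
            sub <- digest(retained$sequence[i],
                list(scheme@step2Enzyme), maxMissed = 0L)
            sub$start <- sub$start + retained$start[i]
            sub$end <- sub$end + retained$start[i]
            sub
        })
        s2 <- do.call(rbind, pieces)
        lab2 <- covers(s2)
        washed <- s2[!lab2, c("start", "end", "sequence"), drop = FALSE]
        retained <- s2[lab2, , drop = FALSE]
    }
    cleaved <- retained[, c("start", "end", "sequence"), drop = FALSE]
    cleaved$labeled <- lapply(seq_len(nrow(cleaved)), function(i)
        labeledPositions[labeledPositions >= cleaved$start[i] &
            labeledPositions < cleaved$end[i]])
    cleaved$remnant <- rep(scheme@remnant@name, nrow(cleaved))
    cleaved$remnant_delta <- rep(scheme@remnant@deltaMass, nrow(cleaved))
    rownames(onbead) <- rownames(washed) <- rownames(cleaved) <- NULL
    list(onbead = onbead, washed = washed, cleaved = cleaved)
}

#' Detectability window for labeled peptides
#'
#' @param minLength,maxLength peptide length bounds (residues).
#' @param minMass,maxMass neutral mass bounds (Da), applied to the peptide
#'   including its probe remnant. Defaults reflect typical LC-MS/MS
#'   practice.
#' @return list of the four bounds.
#' @export
detectabilityWindow <- function(minLength = 6L, maxLength = 40L,
        minMass = 600, maxMass = 6000) {
    stopifnot(minLength <= maxLength, minMass <= maxMass)
    list(minLength = as.integer(minLength),
        maxLength = as.integer(maxLength),
        minMass = minMass, maxMass = maxMass)
}

#' Site detectability across digestion schemes
#'
#' For each annotated site and each scheme, runs the on-bead digestion
#' simulator with that site labeled and asks whether the cleaved-fraction
#' peptide containing the site falls inside the detectability window. This
#' quantifies the coverage gain of sequential digestion: active-site
#' peptides too long for LC-MS/MS under trypsin alone are trimmed by a
#' second protease.
#'
#' @param proteome named character vector or `AAStringSet` of protein
#'   sequences.
#' @param sites data.frame with columns `protein_id` and `site`
#'   (1-based Cys residue number).
#' @param schemes named list of [DigestionScheme-class] objects.
#' @param window a [detectabilityWindow()].
#' @return list with `table` (one row per site x scheme: peptide, length,
#'   mass, detectable) and `coverage` (per-scheme detectable fraction plus
#'   a `union` row).
#' @export
siteDetectability <- function(proteome, sites, schemes,
        window = detectabilityWindow()) {
    proteome <- .asSequences(proteome)
    if (!length(proteome)) stop("empty proteome")
    if (is.null(names(schemes)))
        names(schemes) <- paste0("scheme", seq_along(schemes))
    rows <- list()
    for (i in seq_len(nrow(sites))) {
        pid <- sites$protein_id[i]
        seqi <- proteome[[pid]]
        pos0 <- sites$site[i] - 1L
        for (sn in names(schemes)) {
            sch <- schemes[[sn]]
            fr <- sequentialOnBeadDigest(seqi, pos0, sch)
            stopifnot(nrow(fr$cleaved) == 1L)
            pep <- fr$cleaved$sequence[1]
            mass <- peptideMass(pep) + sch@remnant@deltaMass
            len <- nchar(pep)
            rows[[length(rows) + 1L]] <- data.frame(
                protein_id = pid, site = sites$site[i], scheme = sn,
                peptide = pep, length = len, mass = mass,
                detectable = len >= window$minLength &
                    len <= window$maxLength &
                    mass >= window$minMass & mass <= window$maxMass)
        }
    }
    tab <- do.call(rbind, rows)
    cov <- vapply(names(schemes), function(sn)
        mean(tab$detectable[tab$scheme == sn]), numeric(1))
    key <- paste(tab$protein_id, tab$site)
    unionCov <- mean(vapply(unique(key), function(k)
        any(tab$detectable[key == k]), logical(1)))
    coverage <- data.frame(
        scheme = c(names(schemes), "union"),
        coverage = c(cov, unionCov))
    rownames(coverage) <- NULL
    list(table = tab, coverage = coverage)
}

# coerce AAStringSet or character to a named character vector
.asSequences <- function(x) {
    if (is(x, "AAStringSet")) {
        out <- as.character(x)
        names(out) <- names(x)
        return(out)
    }
    stopifnot(is.character(x))
    x
}
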