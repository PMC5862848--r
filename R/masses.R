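# Monoisotopic mass arithmetic. All masses are monoisotopic; average-mass
# chemistry is deliberately unsupported (the search deltas are monoisotopic).

# monoisotopic element masses (Da), CODATA/IUPAC values
.ELEMENTS <- c(
    C = 12.0,
    H = 1.0078250319,
    N = 14.0030740052,
    O = 15.9949146221,
    S = 31.97207069
)

.WATER <- 18.010565
.PROTON <- 1.007276

# residue (dehydrated) monoisotopic masses for the 20 canonical amino acids
.RESIDUES <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Monoisotopic residue masses
#'
#' Residue (dehydrated) masses of the 20 canonical amino acids; a peptide's
#' neutral mass is the sum of its residue masses plus one water.
#'
#' @return Named numeric vector of 20 residue masses (Da).
#' @examples
#' residueMasses()[["G"]]
#' @export
residueMasses <- function() .RESIDUES

#' Water and proton monoisotopic masses
#'
#' @return Named numeric vector with elements `water` and `proton` (Da).
#' @export
massConstants <- function() c(water = .WATER, proton = .PROTON)

#' Monoisotopic mass from an elemental formula
#'
#' Computes the monoisotopic mass of a formula over C, H, N, O, S. Used to
#' validate registry mass deltas whose composition is known (e.g. the
#' carbamidomethyl group C2H3NO).
#'
#' @param formula character like `"C2H3NO"`; counts default to 1.
#' @return Monoisotopic mass in Da (unrounded).
#' @examples
#' formulaMass("O")       # Met oxidation, 15.9949
#' formulaMass("C2H3NO")  # carbamidomethyl, 57.0215
#' @export
formulaMass <- function(formula) {
    stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
    m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    if (!length(toks) || sum(attr(m, "match.length")) != nchar(formula))
        stop("malformed formula: ", formula)
    total <- 0
    for (tok in toks) {
        el <- gsub("[0-9]", "", tok)
        n <- sub("^[A-Za-z]+", "", tok)
        n <- if (nzchar(n)) as.integer(n) else 1L
        if (!el %in% names(.ELEMENTS))
            stop("unknown element '", el, "' in formula ", formula)
        total <- total + n * .ELEMENTS[[el]]
    }
    total
}

# normalise a mods argument to a data.frame(position, delta, name);
# accepts NULL, that data.frame, or a list of list(position=, mod=)
.modFrame <- function(mods) {
    if (is.null(mods) || (is.list(mods) && !length(mods)))
        return(data.frame(position = integer(0), delta = numeric(0),
            name = character(0)))
    if (is.data.frame(mods)) {
        stopifnot(all(c("position", "delta") %in% names(mods)))
        if (is.null(mods$name)) mods$name <- rep(NA_character_, nrow(mods))
        return(mods[, c("position", "delta", "name")])
    }
    pos <- vapply(mods, function(x) as.integer(x$position), integer(1))
    ms <- lapply(mods, `[[`, "mod")
    data.frame(position = pos,
        delta = vapply(ms, deltaMass, numeric(1)),
        name = vapply(ms, modName, character(1)))
}

# check that each mod sits on a residue its Modification targets
.checkModPlacement <- function(sequence, mods) {
    if (!length(mods)) return(invisible(NULL))
    res <- strsplit(sequence, "")[[1]]
    for (x in mods) {
        p <- as.integer(x$position)
        if (p < 1L || p > length(res))
            stop("modification position ", p, " outside peptide")
        if (!res[p] %in% modTargets(x$mod))
            stop("modification '", modName(x$mod), "' cannot sit on ",
                res[p], " at position ", p)
    }
    invisible(NULL)
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water plus any modification deltas.
#'
#' @param sequence peptide sequence over the 20 canonical amino acids.
#'   Non-canonical letters (U, B, Z, X, ...) are rejected.
#' @param mods modifications attached to the peptide: either a list of
#'   `list(position = i, mod = Modification)` (placement is validated
#'   against the modification's target residues) or a
#'   `data.frame(position, delta)`.
#' @return Neutral monoisotopic mass (Da).
#' @examples
#' peptideMass("GG")  # 132.0535
#' peptideMass("C", list(list(position = 1,
#'     mod = Modification("carbamidomethyl", 57.0215, "C", "fixed"))))
#' @export
peptideMass <- function(sequence, mods = NULL) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (!nzchar(sequence)) stop("empty peptide sequence")
    res <- strsplit(sequence, "")[[1]]
    bad <- setdiff(res, names(.RESIDUES))
    if (length(bad))
        stop("unknown residue letter(s): ", paste(unique(bad),
            collapse = ", "))
    if (is.list(mods) && !is.data.frame(mods) && length(mods))
        .checkModPlacement(sequence, mods)
    mf <- .modFrame(mods)
    if (nrow(mf) && (any(mf$position < 1L) ||
        any(mf$position > length(res))))
        stop("modification position outside peptide")
    sum(.RESIDUES[res]) + .WATER + sum(mf$delta)
}

#' Mass-to-charge ratio of a protonated ion
#'
#' @param neutralMass neutral monoisotopic mass (Da).
#' @param charge positive integer charge state.
#' @return m/z = (neutralMass + charge * proton) / charge.
#' @examples
#' mz(1000, 2)
#' @export
mz <- function(neutralMass, charge) {
    charge <- as.integer(charge)
    if (any(charge <= 0L)) stop("charge must be >= 1")
    (neutralMass + charge * .PROTON) / charge
}

#' Relative mass error in parts per million
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z (> 0).
#' @return signed ppm error, 1e6 * (observed - theoretical) / theoretical.
#' @examples
#' ppmError(500.025, 500.000)  # +50 ppm
#' @export
ppmError <- function(observed, theoretical) {
    if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
    1e6 * (observed - theoretical) / theoretical
}

#' Precursor / fragment match tolerances
#'
#' @param precursorPpm precursor tolerance in ppm (default 50, the search
#'   setting used for ion-trap fragment data).
#' @param fragmentDa fragment tolerance in Da (default 0.8).
#' @return list with elements `precursorPpm` and `fragmentDa`.
#' @export
matchTolerance <- function(precursorPpm = 50, fragmentDa = 0.8) {
    stopifnot(precursorPpm > 0, fragmentDa > 0)
    list(precursorPpm = precursorPpm, fragmentDa = fragmentDa)
}

#' The packaged modification registry
#'
#' Reads the packaged registry of search modifications: the probe-remnant
#' deltas (vinyl sulfone, vinyl methyl ester, propargylamide, the
#' vinyl-pentynyl-sulfone probe with DADPS or DDE linker, hydrolyzed vinyl
#' pentynyl ester), carbamidomethylation, Met oxidation and the Gly-Gly
#' ubiquitination remnant. A user registry in the same TSV format
#' (columns name, delta_mass, targets, kind) can be merged on top; on a
#' name clash the user entry wins.
#'
#' @param userPath optional path to a user TSV merged over the packaged one.
#' @return Named list of [Modification-class] objects.
#' @examples
#' reg <- modificationRegistry()
#' deltaMass(reg$oxidation)
#' @export
modificationRegistry <- function(userPath = NULL) {
    path <- system.file("extdata", "modifications.tsv",
        package = "probescout", mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
        stringsAsFactors = FALSE)
    if (!is.null(userPath)) {
        user <- utils::read.delim(userPath, comment.char = "#",
            stringsAsFactors = FALSE)
        tab <- rbind(tab[!tab$name %in% user$name,
            intersect(names(tab), names(user))],
            user[, intersect(names(tab), names(user))])
    }
    out <- lapply(seq_len(nrow(tab)), function(i) {
        Modification(tab$name[i], tab$delta_mass[i],
            strsplit(tab$targets[i], ",")[[1]], tab$kind[i])
    })
    names(out) <- tab$name
    attr(out, "formula") <- stats::setNames(tab$formula, tab$name)
    out
}

#' The default probe remnant
#'
#' The remnant left on a labeled Cys by the vinyl-pentynyl-sulfone probe
#' after acid cleavage of the DADPS linker (+387.1940 Da).
#'
#' @return A [Modification-class].
#' @export
probeRemnant <- function() modificationRegistry()$vps_dadps_remnant
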