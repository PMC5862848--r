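#' @import methods
NULL

#' Modification: a named monoisotopic mass shift
#'
#' Represents a covalent modification attached to specific residues: a probe
#' remnant left on a labeled Cys after linker cleavage, carbamidomethylation
#' from alkylation, Met oxidation, or the Gly-Gly ubiquitination remnant.
#'
#' @slot name single character identifier.
#' @slot deltaMass monoisotopic mass shift in Da.
#' @slot targets character vector of one-letter residue codes the
#'   modification may sit on.
#' @slot kind `"fixed"` or `"variable"` (search semantics).
#' @exportClass Modification
setClass("Modification",
    representation(
        name = "character",
        deltaMass = "numeric",
        targets = "character",
        kind = "character"
    )
)

setValidity("Modification", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@deltaMass) != 1L || !is.finite(object@deltaMass))
        msg <- c(msg, "'deltaMass' must be a single finite number")
    if (length(object@targets) < 1L ||
        !all(object@targets %in% names(residueMasses())))
        msg <- c(msg, "'targets' must be canonical residue letters")
    if (!object@kind %in% c("fixed", "variable"))
        msg <- c(msg, "'kind' must be 'fixed' or 'variable'")
    if (is.null(msg)) TRUE else msg
})

#' Construct a Modification
#'
#' @param name identifier, e.g. `"carbamidomethyl"`.
#' @param deltaMass monoisotopic mass shift (Da).
#' @param targets residue letters the modification targets.
#' @param kind `"fixed"` or `"variable"`.
#' @return A [Modification-class] object.
#' @examples
#' Modification("carbamidomethyl", 57.0215, "C", "fixed")
#' @export
Modification <- function(name, deltaMass, targets, kind = "variable") {
    new("Modification", name = name, deltaMass = as.numeric(deltaMass),
        targets = targets, kind = kind)
}

setMethod("show", "Modification", function(object) {
    cat(sprintf("Modification '%s': %+0.4f Da on [%s] (%s)\n",
        object@name, object@deltaMass,
        paste(object@targets, collapse = ""), object@kind))
})

#' @describeIn modName accessor for the modification name
#' @export
setGeneric("modName", function(x) standardGeneric("modName"))
#' Accessors for Modification slots
#'
#' @param x a [Modification-class].
#' @return `modName()` the name, `deltaMass()` the monoisotopic shift in Da,
#'   `modTargets()` the targeted residue letters.
#' @name modName
#' @export
setMethod("modName", "Modification", function(x) x@name)
#' @rdname modName
#' @export
setGeneric("deltaMass", function(x) standardGeneric("deltaMass"))
#' @rdname modName
#' @export
setMethod("deltaMass", "Modification", function(x) x@deltaMass)
#' @rdname modName
#' @export
setGeneric("modTargets", function(x) standardGeneric("modTargets"))
#' @rdname modName
#' @export
setMethod("modTargets", "Modification", function(x) x@targets)

#' Enzyme: a site-specific protease
#'
#' C-terminal cleavage rule: the enzyme cuts after any residue in
#' `cleaveAfter` unless the next residue is in `blockedByNext`.
#'
#' @slot name protease name.
#' @slot cleaveAfter residues after which cleavage occurs.
#' @slot blockedByNext residues that suppress cleavage when they follow the
#'   cut site (classically Pro for trypsin and chymotrypsin).
#' @exportClass Enzyme
setClass("Enzyme",
    representation(
        name = "character",
        cleaveAfter = "character",
        blockedByNext = "character"
    )
)

setValidity("Enzyme", function(object) {
    if (length(object@cleaveAfter) < 1L)
        return("'cleaveAfter' must name at least one residue")
    TRUE
})

#' Construct an Enzyme
#'
#' @param name protease name.
#' @param cleaveAfter residue letters after which the enzyme cuts.
#' @param blockedByNext residue letters that block cleavage when following
#'   the cut site.
#' @return An [Enzyme-class] object.
#' @examples
#' Enzyme("trypsin", c("K", "R"), "P")
#' @export
Enzyme <- function(name, cleaveAfter, blockedByNext = character(0)) {
    new("Enzyme", name = name, cleaveAfter = cleaveAfter,
        blockedByNext = blockedByNext)
}

setMethod("show", "Enzyme", function(object) {
    blk <- if (length(object@blockedByNext))
        paste0(", blocked before [", paste(object@blockedByNext,
            collapse = ""), "]") else ""
    cat(sprintf("Enzyme '%s': cleaves after [%s]%s\n", object@name,
        paste(object@cleaveAfter, collapse = ""), blk))
})

#' DigestionScheme: the sequential on-bead digestion workflow
#'
#' Models the on-bead workflow: a first protease step releases unlabeled
#' peptides (the on-bead digestion fraction used for protein identification)
#' while labeled peptides stay bead-bound through the biotin tag; an
#' optional second protease trims the retained peptides (released unlabeled
#' sub-peptides are washed away); finally linker cleavage releases the
#' labeled peptides, each carrying the probe-remnant modification on its
#' labeled Cys.
#'
#' @slot step1Enzymes list of [Enzyme-class] applied jointly in step 1.
#' @slot step1MaxMissed maximum missed cleavages for step-1 search peptides.
#' @slot step2Enzyme an [Enzyme-class], or NULL for immediate linker
#'   cleavage after step 1.
#' @slot step2MaxMissed maximum missed cleavages for step-2 search peptides.
#' @slot remnant the probe-remnant [Modification-class] attached to each
#'   labeled Cys on linker cleavage.
#' @exportClass DigestionScheme
setClass("DigestionScheme",
    representation(
        step1Enzymes = "list",
        step1MaxMissed = "integer",
        step2Enzyme = "ANY",
        step2MaxMissed = "integer",
        remnant = "Modification"
    )
)

setValidity("DigestionScheme", function(object) {
    msg <- NULL
    if (!length(object@step1Enzymes) ||
        !all(vapply(object@step1Enzymes, is, logical(1), "Enzyme")))
        msg <- c(msg, "'step1Enzymes' must be a non-empty list of Enzyme")
    if (!is.null(object@step2Enzyme) && !is(object@step2Enzyme, "Enzyme"))
        msg <- c(msg, "'step2Enzyme' must be an Enzyme or NULL")
    if (object@step1MaxMissed < 0L || object@step2MaxMissed < 0L)
        msg <- c(msg, "missed-cleavage limits must be >= 0")
    if (!"C" %in% object@remnant@targets)
        msg <- c(msg, "'remnant' must target Cys")
    if (is.null(msg)) TRUE else msg
})

#' Construct a DigestionScheme
#'
#' @param step1Enzymes an [Enzyme-class] or list of them, applied jointly.
#' @param remnant probe-remnant [Modification-class] (must target C).
#' @param step2Enzyme optional second-step [Enzyme-class].
#' @param step1MaxMissed,step2MaxMissed missed-cleavage limits used when
#'   enumerating search-candidate peptides (default 2, the conventional
#'   search setting).
#' @return A [DigestionScheme-class].
#' @examples
#' sch <- DigestionScheme(
#'     step1Enzymes = list(getEnzyme("trypsin"), getEnzyme("lysC")),
#'     remnant = probeRemnant(),
#'     step2Enzyme = getEnzyme("gluC"))
#' sch
#' @export
DigestionScheme <- function(step1Enzymes, remnant, step2Enzyme = NULL,
        step1MaxMissed = 2L, step2MaxMissed = 2L) {
    if (is(step1Enzymes, "Enzyme")) step1Enzymes <- list(step1Enzymes)
    new("DigestionScheme", step1Enzymes = step1Enzymes,
        step1MaxMissed = as.integer(step1MaxMissed),
        step2Enzyme = step2Enzyme,
        step2MaxMissed = as.integer(step2MaxMissed),
        remnant = remnant)
}

setMethod("show", "DigestionScheme", function(object) {
    s1 <- paste(vapply(object@step1Enzymes, function(e) e@name,
        character(1)), collapse = "+")
    s2 <- if (is.null(object@step2Enzyme)) "none" else
        object@step2Enzyme@name
    cat(sprintf(
        "DigestionScheme: step1 %s (<=%d missed); step2 %s (<=%d missed); remnant %s (%+0.4f Da)\n",
        s1, object@step1MaxMissed, s2, object@step2MaxMissed,
        object@remnant@name, object@remnant@deltaMass))
})
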