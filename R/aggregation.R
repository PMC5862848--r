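# Aggregation of retained PSMs into per-site records, the high-confidence
# rule, catalytic/non-catalytic classification, and summary counts.

#' Aggregate retained PSMs into labeling-site records
#'
#' Merges PSMs across biological replicates and digestion conditions into
#' one record per (protein, site). A site is high-confidence when it was
#' observed in more than one biological replicate; digestion conditions
#' within a single replicate do not confer high confidence (configurable
#' via `confidenceBy`). PSMs whose localization score falls below
#' `minAscore` are ambiguous at site level and are excluded from site
#' records (they still count as protein-level evidence elsewhere).
#'
#' @param psms data.frame with columns `protein_id`, `site` (1-based),
#'   `replicate`, `condition`, `ascore` and (if present) a logical
#'   `retained` column, in which case only retained PSMs are used.
#' @param minAscore localization-score threshold (default 13,
#'   approximately a tenfold probability difference at p = 0.05).
#' @param minReplicates replicates needed for high confidence (default 2).
#' @param confidenceBy `"replicate"` (default) or `"experiment"`
#'   (replicate x condition pairs).
#' @return data.frame with one row per (protein, site): the replicate and
#'   condition sets observed, observation count, and `high_confidence`.
#' @export
aggregateSites <- function(psms, minAscore = 13, minReplicates = 2L,
        confidenceBy = c("replicate", "experiment")) {
    confidenceBy <- match.arg(confidenceBy)
    stopifnot(all(c("protein_id", "site", "replicate") %in% names(psms)))
    if (any(is.na(psms$replicate))) stop("PSM without replicate id")
    if ("retained" %in% names(psms))
        psms <- psms[psms$retained, , drop = FALSE]
    if ("ascore" %in% names(psms))
        psms <- psms[psms$ascore >= minAscore, , drop = FALSE]
    if (!nrow(psms))
        return(data.frame(protein_id = character(0), site = integer(0),
            replicates_observed = character(0),
            conditions_observed = character(0), n_psms = integer(0),
            high_confidence = logical(0)))
    key <- paste(psms$protein_id, psms$site, sep = "\r")
    recs <- lapply(split(seq_len(nrow(psms)), key), function(ix) {
        reps <- sort(unique(as.character(psms$replicate[ix])))
        conds <- sort(unique(as.character(psms$condition[ix])))
        nunit <- if (confidenceBy == "replicate") length(reps) else
            length(unique(paste(psms$replicate[ix], psms$condition[ix])))
        data.frame(protein_id = psms$protein_id[ix[1L]],
            site = psms$site[ix[1L]],
            replicates_observed = paste(reps, collapse = ","),
            conditions_observed = paste(conds, collapse = ","),
            n_psms = length(ix),
            high_confidence = nunit >= minReplicates)
    })
    out <- do.call(rbind, recs)
    out <- out[order(out$protein_id, out$site), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify a labeling site as catalytic or non-catalytic
#'
#' @param proteinId protein identifier.
#' @param site 1-based Cys position.
#' @param annotations data.frame with columns `protein_id`, `class` and
#'   `catalytic_sites` (comma-separated 1-based positions, possibly empty).
#' @return `"catalytic"`, `"non_catalytic"`, or `"unannotated"` when the
#'   protein is absent from the annotation.
#' @examples
#' ann <- data.frame(protein_id = "UCHL1", class = "UCH",
#'     catalytic_sites = "90")
#' classifySite("UCHL1", 90, ann)   # catalytic
#' classifySite("UCHL1", 152, ann)  # non_catalytic
#' @export
classifySite <- function(proteinId, site, annotations) {
    i <- match(proteinId, annotations$protein_id)
    if (is.na(i)) return("unannotated")
    cat <- annotations$catalytic_sites[i]
    catPos <- if (is.na(cat) || !nzchar(cat)) integer(0) else
        as.integer(strsplit(as.character(cat), ",")[[1]])
    if (site %in% catPos) "catalytic" else "non_catalytic"
}

#' Summarize labeling-site records
#'
#' Counts proteins with at least one high-confidence site, proteins with a
#' high-confidence non-catalytic site, and sites per protein, overall and
#' per protein class.
#'
#' @param records data.frame with columns `protein`, `class`, `site`,
#'   `high_confidence`, `non_catalytic` (as returned by
#'   [loadTable1Fixture()], or built from [aggregateSites()] plus
#'   [classifySite()]).
#' @param dubClasses classes counted as DUB classes.
#' @return list with elements `by_class` (data.frame of per-class protein
#'   counts), `proteins_high_confidence`, `dub_proteins_high_confidence`,
#'   `dub_proteins_high_confidence_non_catalytic`, and `sites_per_protein`
#'   (named integer vector).
#' @export
summarizeSites <- function(records,
        dubClasses = c("USP", "OTU", "UCH", "JOS")) {
    need <- c("protein", "class", "site", "high_confidence",
        "non_catalytic")
    stopifnot(all(need %in% names(records)))
    if (!nrow(records))
        return(list(by_class = data.frame(class = character(0),
                n_proteins = integer(0), n_high_confidence = integer(0),
                n_high_confidence_non_catalytic = integer(0)),
            proteins_high_confidence = 0L,
            dub_proteins_high_confidence = 0L,
            dub_proteins_high_confidence_non_catalytic = 0L,
            sites_per_protein = integer(0)))
    key <- paste(records$class, records$protein)
    byClass <- do.call(rbind, lapply(split(records, records$class),
        function(d) data.frame(
            class = d$class[1L],
            n_proteins = length(unique(d$protein)),
            n_high_confidence = length(unique(
                d$protein[d$high_confidence])),
            n_high_confidence_non_catalytic = length(unique(
                d$protein[d$high_confidence & d$non_catalytic])))))
    rownames(byClass) <- NULL
    dub <- records[records$class %in% dubClasses, , drop = FALSE]
    spp <- vapply(split(records$site, records$protein),
        function(s) length(unique(s)), integer(1))
    list(by_class = byClass,
        proteins_high_confidence = length(unique(
            records$protein[records$high_confidence])),
        dub_proteins_high_confidence = length(unique(
            dub$protein[dub$high_confidence])),
        dub_proteins_high_confidence_non_catalytic = length(unique(
            dub$protein[dub$high_confidence & dub$non_catalytic])),
        sites_per_protein = spp)
}

#' Protein identification by unique-peptide counting
#'
#' Counts unique peptides (distinct sequence + modification state) per
#' protein per sample and flags proteins identified with at least
#' `threshold` unique peptides, the conventional protein-identification
#' rule for the on-bead digestion fraction.
#'
#' @param psms data.frame with `protein_id`, `sequence`, `mods`,
#'   `sample_id` (missing `mods`/`sample_id` are treated as one state/one
#'   sample).
#' @param threshold minimum unique peptides (default 3).
#' @return data.frame with `protein_id`, `sample_id`,
#'   `unique_peptide_count`, `identified`.
#' @export
proteinIdentificationSummary <- function(psms, threshold = 3L) {
    if (!nrow(psms))
        return(data.frame(protein_id = character(0),
            sample_id = character(0), unique_peptide_count = integer(0),
            identified = logical(0)))
    mods <- if ("mods" %in% names(psms)) psms$mods else ""
    sample <- if ("sample_id" %in% names(psms)) psms$sample_id else "all"
    feat <- unique(data.frame(protein_id = psms$protein_id,
        sample_id = sample, pep = paste(psms$sequence, mods)))
    cnt <- stats::aggregate(pep ~ protein_id + sample_id, data = feat,
        FUN = length)
    names(cnt)[3] <- "unique_peptide_count"
    cnt$identified <- cnt$unique_peptide_count >= threshold
    cnt[order(cnt$protein_id, cnt$sample_id), , drop = FALSE]
}
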