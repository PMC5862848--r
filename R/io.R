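# File formats: FASTA proteomes, MGF peak lists, TSV tables, and the
# packaged labeling-site fixture.

#' Read a proteome from FASTA
#'
#' Record ids are the first whitespace-delimited token of the header;
#' sequences are upper-cased. Duplicate ids are an error.
#'
#' @param path FASTA file.
#' @return Named character vector of protein sequences.
#' @export
readProteome <- function(path) {
    aa <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate protein id(s): ", paste(unique(dup),
            collapse = ", "))
    out <- toupper(as.character(aa))
    names(out) <- ids
    out
}

#' Write a proteome to FASTA
#'
#' @param proteome named character vector.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeProteome <- function(proteome, path) {
    aa <- Biostrings::AAStringSet(proteome)
    Biostrings::writeXStringSet(aa, path)
    invisible(path)
}

#' Write spectra to an MGF peak list
#'
#' Minimal MGF: BEGIN IONS / TITLE / PEPMASS / CHARGE / peak lines /
#' END IONS per spectrum.
#'
#' @param spectra list of [Spectrum()] objects.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeMgf <- function(spectra, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (sp in spectra) {
        writeLines(c("BEGIN IONS",
            paste0("TITLE=", sp$id),
            sprintf("PEPMASS=%.6f", sp$precursorMz),
            sprintf("CHARGE=%d+", sp$charge),
            sprintf("%.5f %.2f", sp$peaks$mz, sp$peaks$intensity),
            "END IONS"), con)
    }
    invisible(path)
}

#' Read spectra from an MGF peak list
#'
#' @param path MGF file written by [writeMgf()] or compatible.
#' @return list of [Spectrum()] objects.
#' @export
readMgf <- function(path) {
    lines <- readLines(path)
    starts <- which(lines == "BEGIN IONS")
    ends <- which(lines == "END IONS")
    if (length(starts) != length(ends))
        stop("malformed MGF: unbalanced BEGIN/END IONS")
    lapply(seq_along(starts), function(i) {
        block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
        meta <- grepl("=", block, fixed = TRUE)
        kv <- strsplit(block[meta], "=", fixed = TRUE)
        keys <- vapply(kv, `[[`, character(1), 1L)
        vals <- vapply(kv, `[[`, character(1), 2L)
        pk <- do.call(rbind, strsplit(trimws(block[!meta]), "\\s+"))
        peaks <- data.frame(mz = as.numeric(pk[, 1]),
            intensity = as.numeric(pk[, 2]))
        Spectrum(id = vals[keys == "TITLE"],
            precursorMz = as.numeric(vals[keys == "PEPMASS"]),
            charge = as.integer(sub("\\+$", "",
                vals[keys == "CHARGE"])),
            peaks = peaks)
    })
}

#' Load the packaged labeling-site table
#'
#' The packaged fixture transcribes the published table of probe-labeling
#' sites found in HEK 293T lysate: one row per (protein, site) with the
#' protein class (USP/OTU/UCH/JOS for DUB classes, Other for non-DUBs),
#' the high-confidence flag (site seen in more than one biological
#' replicate) and the non-catalytic flag.
#'
#' @return data.frame with columns `protein`, `class`, `site`,
#'   `high_confidence`, `non_catalytic`, `catalytic_of_non_dub`.
#' @examples
#' tab <- loadTable1Fixture()
#' subset(tab, protein == "UCHL1")
#' @export
loadTable1Fixture <- function() {
    path <- system.file("extdata", "table1_sites.tsv",
        package = "probescout", mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
        stringsAsFactors = FALSE)
    need <- c("protein", "class", "site", "high_confidence",
        "non_catalytic", "catalytic_of_non_dub")
    if (!identical(names(tab), need))
        stop("fixture columns do not match the expected layout")
    if (anyNA(tab$site) || any(tab$site < 1))
        stop("fixture sites must be 1-based positive integers")
    tab
}

#' Headline counts from the packaged labeling-site table
#'
#' Convenience wrapper: [summarizeSites()] on [loadTable1Fixture()],
#' returning the headline numbers — DUB-class proteins with a
#' high-confidence site, DUB-class proteins with a high-confidence
#' non-catalytic site, USP-class proteins with a high-confidence site,
#' and the number of distinct labeling sites on UCHL1.
#'
#' @return named list of counts plus the full per-class table.
#' @export
table1Summary <- function() {
    tab <- loadTable1Fixture()
    s <- summarizeSites(tab)
    usp <- s$by_class[s$by_class$class == "USP", , drop = FALSE]
    list(
        dub_proteins_high_confidence = s$dub_proteins_high_confidence,
        dub_proteins_high_confidence_non_catalytic =
            s$dub_proteins_high_confidence_non_catalytic,
        usp_proteins_high_confidence = usp$n_high_confidence,
        uchl1_sites = length(unique(tab$site[tab$protein == "UCHL1"])),
        by_class = s$by_class)
}

#' Write a feature-count experiment to TSV
#'
#' @param se SummarizedExperiment of counts.
#' @param countsPath counts TSV (proteins x samples).
#' @param metaPath sample metadata TSV (sample_id, condition, replicate).
#' @return Invisibly, `countsPath`.
#' @export
writeFeatureCounts <- function(se, countsPath, metaPath) {
    counts <- SummarizedExperiment::assay(se, "counts")
    utils::write.table(data.frame(protein = rownames(counts), counts,
        check.names = FALSE), countsPath, sep = "\t", quote = FALSE,
        row.names = FALSE)
    cd <- SummarizedExperiment::colData(se)
    utils::write.table(data.frame(sample_id = rownames(cd),
        condition = cd$condition, replicate = cd$replicate), metaPath,
        sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(countsPath)
}

#' Read a feature-count experiment from TSV
#'
#' @param countsPath counts TSV written by [writeFeatureCounts()].
#' @param metaPath sample metadata TSV.
#' @return SummarizedExperiment.
#' @export
readFeatureCounts <- function(countsPath, metaPath) {
    tab <- utils::read.delim(countsPath, check.names = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab[[1]]
    meta <- utils::read.delim(metaPath)
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    featureCountMatrix(counts, meta$condition, meta$replicate)
}
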