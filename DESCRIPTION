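Package: probescout
Title: Reactive-Site-Centric Chemoproteomics Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of activity-based protein profiling experiments that
    identify the residues labeled by covalent probes. Implements in-silico
    sequential on-bead protease digestion with linker cleavage, probe-site
    identification from fragment spectra with binomial site-localization
    scoring and two-tier target-decoy false discovery rate control,
    aggregation of peptide-spectrum matches into high-confidence
    catalytic/non-catalytic labeling-site calls, and feature-count
    enrichment statistics using precision-weighted empirical-Bayes
    moderated t-tests. Includes a synthetic-data generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0)
biocViews: Proteomics, MassSpectrometry, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
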