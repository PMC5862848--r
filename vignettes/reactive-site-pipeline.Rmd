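---
title: "Reactive-site-centric chemoproteomics: models and methods"
author: "probescout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactive-site-centric chemoproteomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probescout)
```

# The problem

Activity-based probes for deubiquitinases (DUBs) are full-length
ubiquitin molecules carrying a Cys-reactive electrophile in place of the
C-terminal Gly. Probe enrichment is commonly read as evidence of enzyme
activity, but the inference only holds if the probe reacted covalently
and at the catalytic Cys. Identifying the labeled residue directly
requires recovering the remnant-modified peptide, which fails for many
DUBs whose active site sits inside a long Lys/Arg-poor stretch: the
tryptic peptide spanning the catalytic Cys is too long for routine
LC-MS/MS. The workflow modeled here solves this with sequential on-bead
digestion — a first trypsin/Lys-C digestion releases unlabeled peptides
for protein identification while labeled peptides stay bound to
streptavidin beads through a biotin tag; a second protease (Glu-C or
chymotrypsin) trims the retained peptides; acid cleavage of the DADPS
linker then releases labeled peptides carrying a defined remnant mass on
the labeled Cys.

`probescout` implements this workflow as testable computation: mass
arithmetic, digestion simulation and scheme planning, spectrum search
with site localization and FDR control, site aggregation, and the
feature-count enrichment statistics. A synthetic-data generator supplies
inputs with ground truth, standing in for the deposited raw data.

# Mass model

All masses are monoisotopic; average-mass chemistry is unsupported
because every search delta in the registry is monoisotopic. Peptide
neutral mass is the sum of residue (dehydrated) masses plus one water
(18.010565 Da); ions are protonated at 1.007276 Da per charge. The
modification registry stores the probe-remnant deltas as constants
(vinyl sulfone +192.0569, vinyl methyl ester +172.0848, propargylamide
+112.0637, vinyl pentynyl sulfone with DADPS linker +387.1940, with DDE
linker +344.1631, hydrolyzed vinyl pentynyl ester +158.0691 Da) together
with carbamidomethylation (+57.0215), Met oxidation (+15.9949) and the
Gly-Gly ubiquitination remnant (+114.0429). Where an elemental
composition is known (the last three), `formulaMass()` recomputes the
delta from atomic masses and the tests require agreement to 4 decimals;
remnants whose post-cleavage composition is not derivable (notably the
DADPS product) are deliberately opaque constants rather than computed
quantities. Non-canonical residue letters (U, B, Z, X) are rejected with
an error instead of being skipped, so malformed input fails loudly.

# Digestion model

Proteases follow C-terminal rules: cleavage after a residue in the
enzyme's cleave-after set unless the next residue is in its blocking
set. Defaults are the Mascot-style conventions: trypsin K/R blocked by
P; Lys-C K unblocked; chymotrypsin F/W/Y/L blocked by P; Glu-C E only,
matching its specificity in ammonium bicarbonate buffer. Whether Glu-C
also cleaves after Asp in that buffer is genuinely open; E-only is the
default and the E+D variant is a constructor flag. Sequences are used as
given (no N-terminal Met clipping). Internally all coordinates are
0-based half-open; every user-facing residue number is 1-based, the
convention of published site tables (e.g. "C90").

`digest()` returns all peptides spanning at most `maxMissed` internal
cut sites. The search default is two missed cleavages, the conventional
search-engine setting.

**The on-bead simulator cleaves to completion.** A design point worth
stating: `sequentialOnBeadDigest()` models the physical digest as
complete cleavage, so the on-bead, washed, and cleaved fractions
partition the protein's residues exactly — a property the tests verify
on random proteins. Missed cleavages are a property of the *search
space* (incomplete digestion is possible, so candidates must include
missed forms), not of the idealized physical partition; modeling missed
cleavage physically would place one residue in several released
peptides at once. The scheme's missed-cleavage limits therefore apply
when enumerating search candidates and in detectability planning.

`siteDetectability()` asks, per site and scheme, whether the
cleaved-fraction peptide containing the site falls in a detectability
window — by default 6–40 residues and 600–6000 Da (neutral, including
the remnant). The window is standard LC-MS/MS practice rather than a
measured instrument property; detectability is monotone in window
widening, which the tests check.

# Site identification

**Scoring.** The match score is the count of theoretical b/y ions
matched to observed peaks within the fragment tolerance (0.8 Da
default), each observed peak usable once. The assignment is computed by
a two-pointer greedy that attains the maximum bipartite matching for
interval-structured graphs; the tests compare it against an exhaustive
matching oracle. This transparent count replaces the original
search-engine score plus discriminant filtering, which is not publicly
specified; the FDR tiers are kept, the discriminant is not reproduced.
Ties between candidates break deterministically: fewer modifications,
then lexicographic sequence. One spectrum yields at most one PSM;
chimeric spectra are out of scope.

**Localization.** For peptides with more than one Cys, each candidate
remnant placement is scored on its site-determining ions (theoretical
m/z values not shared by all placements) against the spectrum filtered
to the top d = 10 peaks per 100 m/z. With k of n determining ions
matched, P = P(X ≥ k; n, p = d/100) and the placement scores
−10·log₁₀P; the reported score is the best-minus-second difference,
capped at 1000, with the single-Cys case assigned the cap directly.
Scores below 13 (≈ a twenty-fold probability difference) leave a PSM's
site ambiguous: it still counts as protein-level evidence but not
toward site records. The score depends only on peak ranks, so it is
invariant to uniform intensity scaling.

**FDR.** Decoys are whole-protein reversals, searched identically.
Peptide-level q at score s is (#decoys ≥ s)/(#targets ≥ s), monotonized
to be non-increasing in score, filtered at 5%; protein-level q is
computed the same way over each protein's best retained peptide score
and filtered at 2%. An empty decoy set yields all-zero q-values with an
explicit "uncalibrated" warning rather than an error, since small
synthetic searches legitimately produce no decoy matches. Post-hoc
gates used with high-resolution precursor data (minimum ion score 10,
±5 ppm) exist as arguments with those defaults reachable but are off in
the default ion-trap-style configuration (50 ppm precursor, 0.8 Da
fragment).

# Aggregation

Site records merge retained, confidently localized PSMs per (protein,
site), uniting replicate and condition sets. "High confidence" means
observed in at least two *biological replicates*: the published rule
counts experiments out of six biological replicates, each employing
three digestion conditions, so two digestion conditions within one
replicate do not qualify. Counting replicate × condition pairs instead
is available via `confidenceBy = "experiment"` for sensitivity
analysis. Classification against an annotation of catalytic Cys
positions yields catalytic / non-catalytic / unannotated. The packaged
fixture `table1_sites.tsv` transcribes the published site table (bold →
high-confidence, star → non-catalytic); `table1Summary()` reproduces
its headline counts (43 DUB-class proteins with a high-confidence site,
11 with a high-confidence non-catalytic site, 27 USP-class, 4 UCHL1
sites).

Protein identification in the on-bead fraction uses the ≥ 3 unique
peptides rule, counting distinct (sequence, modification state) pairs
per sample.

# Enrichment statistics

Features — distinct (peptide form, charge) triples per protein per
sample — are counted for probe vs control samples in three biological
replicates each. Proteins with fewer than three features in total are
discarded. Counts transform to y = log₂((c + 0.5)/(N + 1)·10⁶); a
per-protein least-squares fit on the intercept + condition design gives
residual standard deviations whose square roots are smoothed against
average log-count by lowess (span 0.5, 3 robustifying iterations,
standard settings for this transform); each observation's precision
weight is the predicted sqrt-sd at its fitted log-count raised to the
−4th power. Weighted least squares per protein then yields the log₂
fold change; variances shrink toward the empirical-Bayes prior,
s̃² = (d₀s₀² + d·s²)/(d₀ + d), with d₀ and s₀² from moment-matching the
log residual variances (digamma/trigamma equations, Newton inversion of
the trigamma). The moderated t uses d₀ + d degrees of freedom and
Benjamini–Hochberg adjustment. If the trigamma inversion is infeasible
(log-variance spread below its sampling noise, common under a pure
null) the fit falls back to the common-variance limit d₀ = ∞ with a
warning. Zero-residual proteins have their sd floored at 1e-8 before
trend fitting and are flagged.

Two deliberate simplifications: the design is intercept + condition
only (the published comparison is pairwise, with no batch terms), and
library-size normalization is total count per sample without a trimmed
mean — probe and control libraries differ *by construction* when the
probe enriches its targets, so trimmed-mean normalization would remove
part of the signal. The compositional consequence is visible in the
volcano table: strong positive fold changes on targets are accompanied
by a modest negative shift of the background.

The implementation is written from these formulas; the Bioconductor
reference implementation serves as an independent cross-check in the
test suite (agreement to ~1e-8 on weights, coefficients, moderated t
and p), never as the computation path.

# Synthetic data: what it does and does not emulate

The generator's defaults are the study conditions: 3 probe vs 3 control
replicates; negative-binomial feature counts with mean 50 and
dispersion 0.2 (overdispersion consistent with a mean–variance trend);
log₂ enrichment 3 on true targets; spectra retaining each fragment ion
with probability 0.7 plus five uniform noise peaks and ±3 ppm precursor
jitter; a proteome in which a quarter of proteins are "DUB-like",
carrying a catalytic Cys inside a 50-residue K/R-free window with
nearby Glu residues so the trypsin-only active-site peptide is long and
a Glu-C second digestion trims it — the geometry that motivates
sequential digestion. The control condition plants no covalent labels,
mirroring a negative-control probe that enriches background without
labeling DUBs.

Emulated: cleavage chemistry, remnant masses, fragment presence/absence
noise, count overdispersion, replicate structure. Not emulated:
intensity models beyond presence/absence, retention time, co-isolation
and chimeric spectra, real protein homology (shared peptides), isotope
errors, and real abundance distributions. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
model, not performance on raw instrument data.

All randomness flows through explicit integer seeds; identical
configuration and seed reproduce outputs byte for byte.

# Numerical choices and problem sizes

Fragment matching uses a 0.8 Da tolerance and the precursor filter 50
ppm by default. The localization binomial caps scores at 1000 and
probabilities at 1e-100 to avoid −10·log₁₀(0) overflow. The q-value
monotonization uses running minima over descending score thresholds.
The test suite and the acceptance script size their simulations for
desk-scale runs: digestion is verified against a brute-force cut-site
oracle on ~1000 random sequences of length ≤ 30 across four enzymes and
0–2 missed cleavages; calibration uses 200 null simulations of 500
proteins (empirical type-I error at α = 0.05 within [0.03, 0.07]) and
planted-effect simulations (≥ 90% of enriched proteins at q < 0.05);
the end-to-end run uses a 60-protein proteome, recovering ≥ 95% of
planted sites; realized false-discovery proportion of the peptide tier
is pooled over 200 simulated searches and stays ≤ 0.10.

# Known limitations

* Semi-specific and non-specific cleavage, PTM-dependent cleavage
  suppression, and Met clipping are not modeled.
* The matched-ion-count score is intentionally simple; it does not
  reproduce any proprietary search-engine score, and absolute score
  scales are not comparable across spectra of very different peptide
  lengths.
* Multiply-labeled peptides are searched with one remnant per peptide;
  the simulator likewise emits one spectrum per labeled peptide with a
  single remnant placement.
* The enrichment model has no batch terms, no intensity information,
  and uses total-count normalization (see above).
* The figure-level results of the original study that require the
  deposited raw spectra (full volcano, expression-matched detection
  rates) are outside what synthetic data can reproduce; the pipeline's
  correctness is established by the oracle, calibration and recovery
  properties instead.
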