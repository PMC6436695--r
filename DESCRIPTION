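Package: lcoms
Title: Exact-Mass LC-MS/MS Annotation of Rhizobial Nod Factors
    (Lipochitooligosaccharides)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted identification of rhizobial Nod factors
    (lipochitooligosaccharides, LCOs) from high-resolution LC-MS/MS peak
    lists. Parses and serializes the compact Spaink structure nomenclature,
    derives elemental formulas by composition rules, computes monoisotopic
    and average masses, adduct m/z values, aggregated isotope envelopes and
    glycosidic B/Y fragment ions, enumerates combinatorial candidate
    databases, and matches observed precursors at part-per-million
    tolerance with an isotopic-pattern score gate and optional fragment
    evidence. Includes a data-dependent-acquisition style spectrum
    simulator with ground truth (decoys, mass jitter, envelope distortion,
    noise) for benchmarking, per-condition presence-matrix construction,
    and a downstream differential-expression filtering stage (signed
    fold-change thresholding, Benjamini-Hochberg FDR, replicon summaries,
    delta-delta-Ct fold changes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, readxl, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
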