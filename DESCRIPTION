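Package: pseudolock
Title: Comparative-Evolution and Genomics Toolkit for Pseudoenzyme Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for establishing that a putative enzyme is a pseudoenzyme
    from comparative and genomic evidence. Implements Dollo-parsimony
    reconstruction of single-gain/multiple-loss binary characters (genes,
    domains, active sites) on rooted phylogenies; classification of
    metal-dependent (PPM family) phosphatase sequences as catalytically
    intact or pseudo from conservation of M1/M2/M3 metal-coordination
    positions; phylogenomic profiling of gene presence/absence with a
    Dollo-aware permutation null; somatic mutation-burden and copy-number
    comparison of gene classes (tumor suppressor / oncogene / neutral);
    and scoring of phosphatase assay readouts, including calibration-curve
    rate conversion, inhibitor-based contaminant attribution, and
    differential cysteine-alkylation accessibility calls. A synthetic-data
    module generates every input with known ground truth so the whole
    pipeline can be exercised and calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
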