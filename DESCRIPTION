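Package: slisy
Title: Sequencing-Linked Phage Display Selection Analysis and Antibody
    Characterization Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for sequencing-based phage display affinity maturation
    of single-chain antibody fragments (scFv): design and enumeration of
    site-saturation variant libraries with iterative fixed backbones,
    conversion of segmented UMI-tagged amplicon reads into per-clone
    molecule counts, confidence-bounded binding- and enrichment-ratio
    scoring (SLISY) with 0-100 normalization and backbone selection,
    global 1:1 Langmuir fitting of multi-cycle surface plasmon resonance
    sensorgrams, and deterministic downstream assay summaries (flow
    quadrant percentages, malignant T cell fraction, drug-to-antibody
    ratio, four-parameter logistic IC50). A synthetic-data module
    simulates panning counts, sequencing reads, sensorgrams and assay
    tables so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
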