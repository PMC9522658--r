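Package: kymodec
Title: Singular Value Decomposition of Intravital Line-Scan Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes spatiotemporal fluorescence waveforms recorded by
    line scanning across kidney proximal-tubule cells into spatial and
    kinetic base vectors by singular value decomposition, with rank
    selection based on singular-value energy and singular-vector
    autocorrelation. Includes a compartmental forward simulator of
    endo-lysosomal protein processing (early endosomes, large apical
    vacuoles, lysosomes) with fluorescence self-quenching/unquenching
    physics, line-scan preprocessing (position rescaling, mean binning,
    quality control), whole-tubule kinetic metrics (onset and delay
    detection, axial uptake length, intracellular dispersion), and in
    silico tryptic digestion with monoisotopic peptide masses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
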