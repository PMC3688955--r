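Package: tracemix
Title: Quantifying Length and Substitution Variants of Multicopy Genes from
    Mixed Sanger Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deconvolves direct Sanger sequencing electropherograms of mixed
    amplicons from multicopy genes (ribosomal DNA internal transcribed
    spacers) into the relative abundances of their length (indel) and
    substitution variants.  Per-position expected ("intrinsic") signal
    intensities are calibrated from normalized clone reads; mixtures of
    frame-shifted length variants are fitted to the observed trace by a
    grid search over variant proportions (the proportion model); peak-height
    ratios corrected by intrinsic intensities quantify substitutions,
    including substitutions lying inside frame-shifted mixed regions.
    Includes a synthetic chromatogram generator with known ground truth,
    ITS region annotation by boundary motifs, detection thresholding, and
    assembly and comparison of per-individual ITS heterogeneity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
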