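Package: ms2mol
Title: Small-Molecule Identification from Tandem Mass Spectra by In Silico
    Fragmentation and Sequence Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for attacking the spectrum-to-structure problem of
    metabolomics: recursive in silico fragmentation of small molecules into
    theoretical protonated fragment spectra, molecular formula enumeration
    from exact mass, peak-list parsing and m/z binning, assembly of
    spectrum/SMILES training pairs with depth-wise augmentation, a
    configurable encoder-decoder attention model for peaks-to-SMILES
    translation exercisable at desk scale, and candidate post-processing
    (formula filtering, spectral round-trip ranking, multi-fingerprint
    Tanimoto similarity, and challenge-style evaluation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
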