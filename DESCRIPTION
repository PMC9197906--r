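Package: peakbase
Title: Local Spectral Knowledge-Base Engine for Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A local, embeddable spectral knowledge-base engine for
    metabolomics and related mass-spectrometry / NMR work: a compound
    registry keyed by InChIKey with deduplication and curation workflow,
    multi-technique spectrum cards (LC-MS, GC-MS, FIA, IC, 1D/2D NMR) with
    typed metadata groups, SPLASH hashing for mass spectra, adduct/ion
    annotation mass calculus, tolerance-based peak search, import/export in
    community formats (compound batch CSV, SDF, MassBank record, MSP,
    nmrML-lite), a deterministic fixture generator, a command-line
    interface and a JSON programmatic interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    httpuv
Config/testthat/edition: 3
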