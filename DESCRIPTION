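Package: spectrotype
Title: Species Discrimination from MALDI-ToF Protein Mass Spectra
Version: 0.1.0
Authors@R: person("Spectrotype", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for species discrimination from linear-mode
    MALDI-ToF protein mass spectra (1.5-20 kDa biotyping range): raw-spectrum
    preprocessing (square-root transform, Savitzky-Golay smoothing, SNIP
    baseline estimation, total-ion-current normalization), SNR-based peak
    detection, relative-tolerance peak binning into a feature matrix, Hellinger
    transformation, Ward clustering with multiscale-bootstrap AU/BP edge
    support, diagonal-discriminant t-score feature ranking, non-metric
    multidimensional scaling, homogeneity-of-dispersion and PERMANOVA tests,
    and Kimura 2-parameter genetic distances with complete deletion. Includes a
    synthetic-spectrum generator with species-specific peak fingerprints so the
    whole chain is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
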