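Package: vibrotact
Title: Mechanoreceptor-Based Tactile Estimation from Tracing Vibrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating human tactile evaluation scores from
    vibration signals recorded while a compliant sensor traces a textured
    surface. Implements piecewise log-linear vibrotactile firing-threshold
    curves for the four glabrous-skin mechanoreceptors (Meissner FA I,
    Pacinian FA II, Merkel SA I, Ruffini SA II), converts strain-gauge
    voltage to displacement and displacement traces to Hamming-windowed
    single-sided amplitude spectra, integrates the spectrum-over-threshold
    region into firing-combination subarea features, analyses
    semantic-differential sensory panels (Ward clustering of subjects,
    correlation-matrix PCA with an eigenvalue-greater-than-one rule), and
    relates features plus dynamic friction to per-sample principal-component
    scores through exhaustive linear, logarithmic, interaction and
    polynomial regression with leave-one-sample-out model selection.
    Includes synthetic generators for tracing vibrations and sensory panels
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
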