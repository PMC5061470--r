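Package: probetools
Title: Quantitative Binding Characterization for Chemical Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the biophysical and cellular characterization
    of small-molecule chemical probes against protein target panels, built
    around bromodomain inhibitor profiling. Implements two-state thermal-shift
    (differential scanning fluorimetry) melt-curve fitting with replicate
    delta-Tm summaries, single-site isothermal titration calorimetry in
    reverse-titration geometry with dilution-heat correction and full
    thermodynamic decomposition (delta-G = delta-H - T delta-S = -RT ln KB),
    FRAP chromatin-displacement quantification with double normalization and
    recovery half-times, vehicle-normalized viability dose-response fitting,
    and Chou-Talalay median-effect combination-index analysis. Every input
    modality has a matching synthetic-data generator with serialized ground
    truth, so parameter-recovery behaviour is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
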