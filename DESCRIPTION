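Package: ppasym
Title: Superior-Inferior Macular Thickness Asymmetry for the 8x8 Posterior Pole Grid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing superior-inferior thickness asymmetry of the
    macula on the Spectralis-style 8x8 posterior pole grid across ten retinal
    layer segmentations. Computes per-cell-pair paired statistics over a
    cohort, builds normative reference databases from the 2.5th and 97.5th
    percentiles of the asymmetries, classifies new eyes against a database,
    renders significance-masked asymmetry heatmaps and device-style maps, and
    simulates calibrated synthetic cohorts for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
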