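Package: irheart
Title: Stain-Free FT-IR Chemical Imaging Histology for Cardiac Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for histologic analysis of Fourier-transform infrared
    (FT-IR) hyperspectral images of endomyocardial biopsy sections without
    staining. Provides ENVI-style cube input/output, tile stitching and
    spatial binning, a synthetic tissue-phantom generator with ground truth,
    amide-I masking and two-point baseline preprocessing, four families of
    spectral metrics (peak height ratios, band-area ratios, centers of
    gravity), a weighted Gaussian naive-Bayes per-pixel classifier with
    AUC-based metric selection, ROC / probability-of-detection evaluation,
    confusion tables, lymphocyte-infiltration rejection calls, and
    pseudo-color rendering of classified tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
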