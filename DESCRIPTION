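Package: hobdcs
Title: Cerebral Blood Flow Response to a Head-of-Bed Challenge Measured
    by Diffuse Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microvascular cerebral blood flow (CBF)
    responses to a head-of-bed (HOB) orthostatic challenge measured with
    diffuse correlation spectroscopy (DCS). Implements the semi-infinite
    correlation diffusion forward model and the inverse fit of intensity
    autocorrelation curves to a blood flow index (BFI), stage windowing and
    normalisation of BFI traces into relative CBF endpoints, a synthetic
    cohort generator emulating obstructive sleep apnea (OSA) severity
    groups with nocturnal oximetry coupling, and the accompanying
    nonparametric statistics battery (Kruskal-Wallis with pairwise
    Bonferroni, Wilcoxon tests, Spearman correlation, forward-stepwise
    linear modelling, bootstrap confidence intervals).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
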