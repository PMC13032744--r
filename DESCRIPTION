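Package: spinefate
Title: Synaptic Calcium Event Extraction and Longitudinal Spine-Fate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-photon calcium imaging of dendritic
    spines in organotypic slice cultures: polynomial baseline detrending,
    Okada denoising, dF/F conversion, sparse non-negative AR(1)
    deconvolution (OASIS-style pool merging with an s_min amplitude
    threshold), photobleaching biexponential modelling, longitudinal spine
    matching with survival annotation, astrocyte-proximity classification,
    phosphatidylserine-probe intensity quantification, and hierarchical
    (animal/slice nested) permutation inference. Includes a synthetic-data
    generator that emulates the full data structure - Poisson synaptic
    event trains, GECI transient kernels, baseline drift, biexponential
    bleaching, treatment-dependent rate changes and survival outcomes -
    carrying ground truth so every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
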