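Package: octmorph
Title: Interface Detection and Surface Morphometry for Layered OCT Volumes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Adaptive interface detection and structural-parameter
    quantification for optical coherence tomography (OCT) volumes of
    layered samples such as tissue-engineered (artificial) skin. Detects
    the upper and lower interface in every A-scan by a two-stage
    (coarse/fine) peak-pair search robust to speckle, stratum-corneum
    multi-spikes and basement-membrane echoes; converts interface maps to
    physical thickness via the axial pixel pitch and refractive index;
    flattens the upper surface by bivariate cubic least squares; and
    computes areal roughness parameters (Ra, Rq, Rsk) over a circular
    region of interest. Ships a synthetic OCT phantom generator with
    exact ground truth (roughness plates and skin-like random surfaces)
    for end-to-end parameter-recovery testing, verification statistics
    against nominal roughness standards, and one-way and repeated-measures
    ANOVA helpers for longitudinal culture-cycle comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    tools,
    methods,
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, ImageImport, Segmentation, FeatureExtraction
Collate: 
    'octmorph-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'detect.R'
    'morphometry.R'
    'phantom.R'
    'stats.R'
    'volume-io.R'
    'pipeline.R'
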