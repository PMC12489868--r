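Package: mocsClahe
Title: Multi-Objective Cuckoo Search Optimisation of Rayleigh CLAHE for
    Vascular Conjunctival Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Contrast enhancement of bright-background microvascular images
    (bulbar conjunctiva imaged with a functional slit lamp biomicroscope)
    using contrast-limited adaptive histogram equalization (CLAHE) with a
    Rayleigh-shaped output histogram, where the tile grid, clip limit and
    Rayleigh alpha are tuned per image by a multi-objective cuckoo search
    (MOCS) that maximises gray-level co-occurrence matrix (GLCM) contrast
    while minimising a fast noise variance estimate (FNVE). Includes
    sharpness-based frame selection for short video sequences, exposure
    classification, full-reference quality metrics (PSNR, global SSIM),
    a synthetic conjunctiva phantom generator with known ground truth,
    and an end-to-end pipeline with batch summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ImageEnhancement, Preprocessing, Software
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-filtering.R'
    'imaging.R'
    'io.R'
    'clahe.R'
    'objectives.R'
    'mocs.R'
    'quality.R'
    'phantom.R'
    'pipeline.R'
    'mocsClahe-package.R'
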