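Package: tubulemorph
Title: Morphometry of Microtubule Bundles from Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies microtubule bundling from dSTORM/SMLM localization
    tables: histogram reconstruction at a chosen pixel size, multi-scale
    Hessian (Frangi) vesselness enhancement with global thresholding,
    skeletonization and branch decomposition, rotation of straight branches
    into grid alignment via the localization list, and tubule width, length
    and intensity measurement by pixel counting. Also implements the
    companion confocal quantifications (3D Manders colocalization
    coefficients, ROI percent-volume and mean-intensity) and nonparametric
    comparison of morphometry distributions (Kruskal-Wallis with an exact
    permutation option). A synthetic-data module generates ground-truthed
    localization tables and two-channel confocal stacks so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
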