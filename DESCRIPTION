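Package: standiv
Title: Diversity-Productivity Analysis for Planted Tree Diversity Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for planted tree diversity (TreeDivNet-style)
    experiments: plot productivity as annual basal-area increment from
    individual-tree inventories (multi-stem aggregation, subsample
    adjustment), functional identity and diversity metrics (community
    weighted means, functional dispersion) and structural diversity (Gini
    coefficient and coefficient of variation of tree heights), additive
    Loreau-Hector partitioning of net diversity effects into selection and
    complementarity components, Gaussian mixed models with
    richness-dependent residual dispersion, and piecewise structural
    equation models with d-separation tests combined via Fisher's C.
    Includes a synthetic experiment generator with known ground truth for
    end-to-end testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmmTMB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
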