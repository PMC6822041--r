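Package: clawmorph
Title: Geometric and Traditional Morphometrics of Avian Pedal Claws
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying avian pedal claw shape from landmark data.
    Implements the traditional inscribed-circle arc protocol (dorsal arc
    angles of the bony core and keratinous sheath, core-to-sheath length
    ratio), generalized Procrustes analysis with bending-energy sliding of
    semilandmarks over an 83-point bony-core/keratinous-sheath landmark
    scheme, and the phylogenetic comparative statistics used to relate claw
    shape to ecology: PGLS with maximum-likelihood Pagel's lambda,
    simulation-based phylogenetic ANOVA, multivariate phylogenetic signal
    (K-mult), phylogenetic Procrustes ANOVA, covariance-ratio modularity
    tests, phylogenetic two-block partial least squares, and a phylogenetic
    paired t test. A fully parameterized synthetic-claw generator (nested
    circular-arc outlines, Brownian-motion species means on simulated trees,
    ecological group structure, weak allometry, intraspecific noise) makes
    every stage testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
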