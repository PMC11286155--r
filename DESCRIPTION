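Package: cranioload
Title: Developmental Finite-Element Analysis of Masticatory Loading on the
    Infant Cranium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the mechanical loading of the infant cranium by the
    masticatory muscles over the first 48 months of life. Provides a
    parametric, bilaterally symmetric skull surrogate with age-dependent
    suture patency; estimation of temporalis, masseter and medial pterygoid
    peak forces from anatomical muscle cross-sectional areas via a muscle
    stress factor; monotone growth regression of per-side muscle forces with
    bootstrap confidence bands; a small-strain linear-elastic finite-element
    engine on labelled tetrahedral meshes with age-dependent bone and
    cranial-joint moduli; estimation of the minimum temporal-fascia force
    that balances the zygomatic arch against masseter pull; and a bite
    pipeline that predicts bite forces, temporomandibular joint reactions
    and von Mises strain/stress fields under three bite modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    pracma,
    splines,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
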