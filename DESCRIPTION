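Package: commass
Title: Centre-of-Mass Estimation by Suspension, Reaction-Board Scales and
    Volumetric Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements three classical methodologies for estimating the
    centre of mass (CoM) of rigid and segmented bodies: suspension (pairwise
    closest point of approach between 3D string lines), the two-scale
    reaction-board method with reversed-repeat bias cancellation, and digital
    volumetric modelling (exact mass properties of closed triangle meshes with
    composite air-cavity subtraction and per-segment densities). Includes
    rigid least-squares registration of labelled marker captures, posture-shift
    quantification, reference geometric-centre constructions, error and
    repeatability metrics, and a seeded synthetic-experiment generator that
    produces virtual specimens with analytically known CoM so the comparative
    accuracy of the methods can be studied end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
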