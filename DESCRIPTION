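Package: cueweights
Title: Constrained Vector-Sum Estimation of Depth-Cue Weights from
    Perceived Surface Orientations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing slant/tilt cue-combination experiments in
    which binocular disparity and texture gradients specify conflicting 3D
    surface orientations. Implements the constrained vector-sum model that
    estimates texture and disparity weights from a perceived surface normal
    under a unit-norm constraint (pseudo-inverse, closed-form line-ellipse
    tangency, and Levenberg-Marquardt solvers), the cue-conflict stimulus
    geometry (Voronoi textures, projector back-projection, stereo
    projection), factorial trial designs for judgment and visuomotor
    training phases, a von Mises-Fisher synthetic observer with a
    parametric disparity-weight field, and an analysis pipeline (per-trial
    weight estimation, cell aggregation, log-slant trend fits with
    subject-level bootstrap, and paired sign-flip permutation tests with
    max-T familywise correction for pre/post cue-reweighting).
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
    withr
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
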