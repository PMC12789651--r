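Package: ovicrypt
Title: Predator-Vision Analysis of Egg Camouflage Against Natural Backgrounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how well ground-nesting birds' eggs match their
    nest backgrounds in the eyes of their likely predators.  Calibrated
    nest photographs (or synthetic stand-in scenes generated by the
    package) are converted to per-pixel cone catches for avian,
    mammalian-carnivore and human visual systems; colour is summarised by
    luminance and opponent (red-green, yellow-blue) channels and visual
    texture by a 6-scale x 8-orientation log-Gabor filter bank reduced by
    principal component analysis.  Discriminability of eggs from
    egg-shaped background samples is then assessed with linear mixed
    models, MANOVA (Pillai's trace), leave-one-nest-out cross-validated
    binomial mixed-model classifiers, confusion summaries against the
    no-information rate, and ROC curves, together with acuity-based
    estimates of the distance at which pattern elements are resolvable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
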