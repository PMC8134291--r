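Package: cycleEMT
Title: Cycle-Consistent Adversarial Compensation of Electromagnetic Tracking Distortion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Online compensation of C-arm-induced electromagnetic tracking (EMT) error by
    unpaired domain translation. Tracked points (position, quality estimate, orientation)
    measured at the bedside are translated into their distortion-free laboratory equivalents
    with a pair of small cycle-consistent adversarial networks that adjust only the z,
    quality and orientation channels, leaving x and y untouched; residual in-plane error is
    removed by a post-hoc linear regression. Includes a parametric distortion-field
    simulator and grid-phantom acquisition model for end-to-end evaluation,
    displacement-based accuracy metrics, deep-ensemble predictive uncertainty, and an
    experiment runner with CSV/JSON/YAML interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'acquisition.R'
    'datamodel.R'
    'distortion.R'
    'experiment.R'
    'finetune.R'
    'grid.R'
    'metrics.R'
    'networks.R'
    'trainer.R'
    'utils.R'
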