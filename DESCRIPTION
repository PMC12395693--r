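Package: plaquescope
Title: Quantification of Amyloid Plaque and Microglia Pathology in Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the image-quantification procedures
    used to characterise amyloid plaque pathology and plaque-microglia
    interactions in confocal fluorescence stacks: maximum-intensity
    projections, automatic thresholding (IsoData, Triangle, mean + k SD),
    connected-component particle analysis, radial intensity profiles and
    plaque-compaction slope fitting, angular barrier-coverage of plaques by
    microglial processes, AND-mask colocalization, axonal-spheroid area
    scoring, and RNA in situ spot-to-nucleus assignment. Companion routines
    cover the non-imaging assays of a typical plaque-pathology study:
    microdialysis clearance kinetics, qPCR fold changes by the delta-delta-Ct
    method, and novel-object-recognition metrics. A synthetic confocal-scene
    generator with an exact ground-truth manifest supports end-to-end
    validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
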