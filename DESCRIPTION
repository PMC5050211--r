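Package: biofilmcubes
Title: Cube-Based Quantification of Bacterial Biofilm Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric quantification of static submerged bacterial biofilms
    from multi-channel 3D confocal fluorescence stacks: isotropic upsampling,
    averaging-filter denoising, three-class Otsu segmentation, dissection of
    the binary biomass map into ~1 micrometre cubes, local-density estimation
    in a 3 micrometre ball, surface height and roughness maps, expression
    profiles versus depth and local density, dual-reporter cube classification
    and TIMER orange/green growth-rate ratios. Also implements the matching
    flow-cytometry event analysis (background subtraction, biexponential
    display scaling, ON/OFF threshold gating) and a seeded synthetic-scene
    generator that renders ground-truthed biofilm stacks and event tables for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
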