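Package: centrotrack
Title: Tracking and Biphasic Kinematics of Clustering Centrosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how supernumerary centrosomes cluster into a
    pseudo-bipolar spindle from 4D live-cell imaging. Provides subpixel 3D
    Gaussian spot localization of centrin-GFP-like point sources, anchor-frame
    propagated detection with gated global nearest-neighbour linking, pair
    separation kinematics (cluster completion, search-and-capture versus
    motorized phase segmentation, mean square displacement, aligned population
    statistics), tripolar spindle smallest-angle analysis, and AFM
    force-curve postprocessing with conical Sneddon-model elasticity fits.
    A synthetic data generator with known ground truth (biphasic pair
    trajectories, rendered image stacks, tripolar geometries, force curves)
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
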