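Package: transcallosal
Title: Trans-Callosal Cortical Connectivity Mapping and Virtual Callosotomy
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps diffusion-tractography streamline endpoints onto triangulated
    cortical mid-surfaces, quantifies callosal connectivity coverage per
    hemisphere and per resting-state subnetwork (Yeo 7/17), subdivides the
    corpus callosum along its principal axis, and simulates progressive
    anterior callosotomy as a virtual lesion, predicting subnetwork
    disruption profiles. Includes native readers and writers for NIfTI-1,
    TCK, GIFTI, OFF and PLY, a seeded synthetic-data generator with planted
    ground truth, and a toy fixed-step Euler streamline tracker.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
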