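Package: txmquant
Title: Simulated Transmission X-Ray Microscopy and Nanoparticle Cluster
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how reliably intracellular metal-nanoparticle
    clusters can be counted, sized and localized from full-field
    transmission X-ray microscopy (TXM). The package generates voxelized
    single-cell phantoms with ground-truth cluster catalogs, forward-models
    absorption-contrast projection series (Beer-Lambert, parallel beam,
    optional photon noise and detector blur), reconstructs limited-angle
    tomograms by filtered back-projection, segments clusters by grey-value
    thresholding with connected-component labeling, estimates per-cluster
    sizes from moment-equivalent ellipses and ellipsoids, measures
    nucleus-relative cluster positions, and summarizes per-cell cluster
    counts and size distributions, including the systematic differences
    between quantification on single 2D projections and on 3D
    reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
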