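Package: contourdyn
Title: Polar Contour Fluctuation Dynamics of Adherent Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies adhesion, spatio-temporal shape dynamics and motility
    of single cells imaged label-free on ligand-functionalized supported
    membranes. Segments dark adhesion footprints from time-lapse image
    stacks, extracts closed cell contours with area, perimeter, circularity
    and elongation, builds polar amplitude maps of radial shape fluctuations
    and their normalized spatio-temporal autocorrelation with peak
    localization, tracks center-of-mass trajectories and mean migration
    speed, and estimates the joint distribution of contour deformation and
    motility direction including symmetry-break detection. A synthetic-data
    generator produces ground-truth contour series, rendered image stacks
    and population adhesion kinetics so the whole pipeline is testable
    without external data. Includes a ligand-spacing design utility for
    biotin-anchored ligands in supported lipid bilayers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
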