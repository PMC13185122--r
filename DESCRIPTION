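Package: dlntraj
Title: Trajectory Analysis for DNA-Corralled Lipid Nanodiscs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of discoidal lipid
    bilayer patches stabilized by PEG-functionalized DNA minicircles
    (DNA-lipid nanodiscs). Implements solvent-accessible surface area and
    the occluded-fraction statistic for lipid tails, motif-resolved atom
    contact counts, leaflet assignment with edge-distance regionalization
    and debounced lipid flip counting, bilayer thickness via per-leaflet
    Gaussian fits, area per lipid, sphere-fit curvature, lateral diffusion
    coefficients from mean-square displacement, a swing-twist tilt
    collective variable, and nanodisc design arithmetic. A seeded
    synthetic-membrane generator produces coarse bilayer-patch
    trajectories with known ground truth so every analysis is verifiable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
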