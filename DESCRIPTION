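Package: spheromap
Title: Spatial Identity Mapping of Stem-Cell Spheroids onto a 3D Embryo Reference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to authenticate in-vitro spheroid cultures against an in-vivo
    primate embryo reference. Implements spatial identity mapping (pseudo-bulk
    Pearson correlation against spatially anchored embryo samples, interpolated
    over a triangulated embryo surface by Gaussian process regression), dynamic
    spatial identity mapping of perturbation-induced fate shifts, an embryonic
    disc versus amnion lineage coordinate system (canonical correlation gene
    selection, principal components, and a linear support-vector decision
    boundary), spheroid image morphometrics (nuclear orientation, epithelial
    thickness, channel intensities) with the associated statistical tests, and
    a fully synthetic data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
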