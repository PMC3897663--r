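Package: tubeorient
Title: Depth-Resolved Smooth Muscle Cell Orientation in Tubular Organs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantifies smooth muscle cell (SMC) orientation across the wall of
    an intact tubular organ (e.g. rat ureter) from 3D nucleus-stained
    microscopy stacks acquired as flat optical sections of a curved wall.
    Provides Hessian-based "cellness" filtering to segment elongated nucleus
    profiles slice by slice, a cylindrical-wall region-of-interest model that
    limits depth crosstalk and guarantees tissue filling, moment-tensor
    orientation estimation with an anisotropy filter for round nuclei, and
    depth-resolved axial circular statistics: a wrapped two-dimensional kernel
    density estimate over (normalized depth, angle) with octile curves,
    circular standard deviation profiles, per-stack dispersion tables, and
    cell-density profiles. Includes a synthetic stack simulator with known
    ground truth so the whole pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    utils,
    stats,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
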