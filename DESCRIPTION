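Package: cororeg
Title: 2D/3D Coronary Artery Centerline Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registration of 3D coronary-artery centerline trees (from CT
    angiography) onto 2D X-ray angiography centerlines. Implements C-arm
    perspective projection from DICOM positioner geometry, bounded six
    degree-of-freedom rigid alignment with a direction-set (Powell)
    optimizer, graph-based reconstruction of corrupted 2D vessel topology
    into candidate line chains, tangent-window point matching,
    multi-feature candi-line similarity selection, and nonrigid deformation
    of the 3D centerline by gradient descent on snake-type continuity,
    curvature and image energies. Includes a seeded synthetic vascular-tree
    simulator with ground-truth rigid/nonrigid deformations for validation,
    segmentation loss functions (binary cross-entropy and chamfer-based
    shape loss), mask skeletonization, and evaluation metrics (marker ADD,
    point/bifurcation precision-recall at metric tolerances).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
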