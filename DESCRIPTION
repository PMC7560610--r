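Package: multireg
Title: Multimodal Co-Registration of In Vivo and Ex Vivo Rodent Brain Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chains the practical registration steps needed to compare in vivo
    radiologic images (PET, T2-weighted MRI) of rodent brain tumors with ex
    vivo optical images of cleared 1-mm tissue slices: masked
    mutual-information rigid registration of PET to in vivo MRI via a fiducial
    loop phantom, masked 12-degree-of-freedom affine registration of in vivo
    to ex vivo MRI to absorb tissue shrinkage, slice-block matching of
    pathology slabs to MRI slices, and per-slice 2D landmark similarity
    registration of fluorescence images. Provides threshold-based tumor
    segmentation against a contralateral reference, paired-landmark error and
    surface-distance agreement metrics, brain-volume change, and a synthetic
    rodent-brain phantom with known ground-truth transforms so the whole
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    tiff,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
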