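Package: strokevol
Title: Segmentation-Based Volume Estimation for Acute Ischemic Stroke on
    Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating acute ischemic stroke lesion volume from
    diffusion-weighted MRI. Implements an indirect route (2D encoder-decoder
    segmentation of slice triplets followed by DICOM-metadata-driven pixel
    volumetry) and a direct route (patch-based 3D segmentation), together
    with a synthetic DWI phantom generator with analytically known lesion
    volumes, minimal DICOM series input/output, HDF5 caching, Dice-loss
    training of small U-Net models on the CPU, and the segmentation and
    volumetry evaluation metrics (sensitivity, the precision-style
    specificity variant, F1, Jaccard, volume similarity, mean absolute
    error in cc).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    rhdf5,
    jsonlite,
    yaml,
    tibble,
    generics,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    RNifti
Config/testthat/edition: 3
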