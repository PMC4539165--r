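Package: strokemorph
Title: Phase-Based Metamorphosis Analysis of Ischemic Stroke Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint geometric and photometric (metamorphosis) registration of
    longitudinal stroke MRI, in the large-deformation diffeomorphic setting.
    Estimates an optimal intensity/velocity path morphing an acute
    diffusion-weighted lesion image into subacute and final observations,
    derives signed lesion deformation maps (time-integrated squared speed,
    signed by expansion or contraction), extracts highly dynamic lesion
    regions by a mean +/- standard-deviation speed rule, builds relative
    mean-transit-time (rMTT) perfusion maps by contralateral mirror
    normalization, and relates deformation magnitudes to rMTT via Gaussian
    least-squares fits with peak +/- sd intervals. A synthetic-data module
    generates longitudinal cases with known ground truth so the full pipeline
    is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    minpack.lm,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
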