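Package: tractrepro
Title: Scan-Rescan Reproducibility of CSD-Based Tractography on Synthetic Diffusion Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired-session diffusion-weighted MRI phantoms
    (multi-tensor signal, Rician noise, electrostatically spread gradient
    schemes), fits the diffusion tensor (FA/ADC) and constrained spherical
    deconvolution fiber orientation distributions, performs probabilistic
    streamline tractography with seed/target region logic and whole-mask
    seeding for track-density imaging, converts tractograms to density maps
    and binary tract segmentations, and quantifies test-retest
    reproducibility of tract morphology and metrics with the Dice similarity
    coefficient, within-subject coefficient of variation, and intraclass
    correlation coefficient, including paired t-tests and Bland-Altman
    summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
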