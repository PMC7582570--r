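Package: hrvauth
Title: Continuous Biometric Authentication from Heart-Rate-Variability
    Signals via Biorthogonal Wavelet Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for continuous authentication of
    m-health data streams using heart-rate-variability (HRV) signals as a
    biometric. Signals sampled at 8 Hz are segmented into short windows,
    decomposed with spline biorthogonal wavelet filter banks (bior1.1
    through bior6.8) into three levels of approximation and detail
    sub-bands, summarised by a fixed set of statistical features, and
    scored by per-subject feedforward neural networks. Verification
    performance is reported as false-acceptance/false-rejection curves,
    equal error rates (EER), feature-level sub-band fusion comparisons,
    and threshold-based authentication success rates. A seeded
    multi-subject HRV simulator with controllable between-subject
    separation provides study-scale synthetic cohorts for end-to-end
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nnet,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
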