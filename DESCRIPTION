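Package: radstab
Title: Stability of Radiomic Features Between Paired MRI Acquisitions
Version: 0.1.0
Authors@R: person("radstab", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Extracts a 595-feature radiomics catalog (first-order,
    gray-level co-occurrence, run-length, size-zone, neighbouring gray tone
    difference, local binary pattern, and two-level undecimated wavelet
    subband texture features) from 3D volumes with lesion masks, quantifies
    per-feature test-retest agreement between a conventional and a fast
    acquisition with Lin's concordance correlation coefficient, classifies
    features as stable (CCC > 0.85), and compares stable-feature proportions
    between fast sequences with McNemar's test. Includes a synthetic
    paired-acquisition cohort generator (textured hyperintense lesion
    phantoms degraded by matrix reduction, blur and noise) so the whole
    pipeline is testable without patient data, plus minimal NIfTI-1 I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
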