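Package: ssrgblup
Title: Single-Step Genomic BLUP and Association Analysis for Multiallelic
    SSR Markers in Multi-Harvest Trials
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Maintainer [aut, cre]
Maintainer: Package Maintainer <maintainer@example.org>
Description: Tools for genomic evaluation of perennial-forage trials
    genotyped with multiallelic simple sequence repeat (SSR) markers.
    Expands SSR allele calls into binary presence/absence markers with
    quality control and frequency-threshold imputation, builds genomic
    (G), blended (G*) and single-step inverse (H-1) relationship
    matrices covering genotyped and ungenotyped individuals, fits
    multi-random-effect linear mixed models by restricted maximum
    likelihood (EM with optional average-information acceleration) with
    likelihood-ratio tests and prediction-error-variance accuracies,
    runs per-harvest single-marker association scans with false
    discovery rate control, profiles pairwise linkage disequilibrium,
    and simulates study-shaped data sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
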