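Package: aeroquant
Title: Targeted LC-HRMS Quantification of Pharmaceuticals in Plant Tissue
Version: 0.1.0
Authors@R:
    person("Aeroquant", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Internal-standard response-factor quantification for targeted
    LC-HESI-HRMS peak-area tables, as used in studies of pharmaceutical
    uptake by plants. Computes per-compound response factors from solvent
    calibration standards with iterative trimming of calibration points
    (30 percent deviation rule), evaluates matrix effects against
    matrix-matched standards with a 20 percent decision rule for switching
    quantifiers, propagates per-sample limits of quantification and
    detection from the lowest retained calibration point, and summarises
    method performance (recovery, precision, response-factor drift over an
    injection sequence). A post-quantification layer computes leaf/root
    partitioning, metabolite-to-parent ratios and Henderson-Hasselbalch
    ionization fractions. A seeded synthetic-data generator emulates the
    full study design (nine-point calibration, matrix standards,
    heptaplicate spiked quality controls) so that every pipeline stage is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
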