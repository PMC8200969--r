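Package: dermaflux
Title: Quantification of Facial Skin Pore Area, Roughness and Redness with
    Longitudinal Fluctuation Analytics
Version: 0.1.0
Authors@R:
    person("dermaflux", "maintainers", email = "maintainers@dermaflux.invalid",
           role = c("aut", "cre"))
Description: Gray-reference color calibration, pore-area detection on
    edge-enhanced binary images, shadow-spectrum surface roughness, and
    Fourier-filtered hemoglobin redness scoring for at-home facial skin
    photography, together with repeated-measures fluctuation analytics
    (three daily timepoints, weekly averages, delta fluctuation,
    baseline/treatment comparisons) and a synthetic patch and cohort
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    jpeg
Config/testthat/edition: 3
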