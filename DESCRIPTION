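Package: co2perf
Title: Two-Dimensional Perfusion Angiography Analysis for CO2 Digital
    Subtraction Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies contrast transit in digital subtraction angiography
    (DSA) runs by 2D-perfusion angiography (2D-PA): per-ROI time-density
    curves, time to peak (TTP), peak density (PD) and area under the curve
    (AUC), color-coded parametric maps, outflow/inflow ratio endpoints
    across paired pre-/post-revascularization runs, and exact Wilcoxon
    signed-rank comparison of the paired ratios. Includes a synthetic
    CO2-angiography phantom of a stenosed vessel with known ground truth,
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
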