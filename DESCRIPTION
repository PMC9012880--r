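Package: capspec
Title: Capillary Hemodynamics and Microvascular Hemoglobin Spectroscopy
    from Intravital Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies skeletal-muscle microvascular function from
    dual-wavelength (438/450 nm) transillumination video and visible-band
    continuous-wave spectroscopy. Builds space-time images (kymographs)
    along capillary centerlines and extracts red blood cell velocity,
    lineal density, hematocrit, supply rate and oxygen saturation from
    the 438/450 nm optical-density ratio; derives microvascular
    hemoglobin dynamics as Beer-Lambert optical-density changes from mean
    frame intensity and from six isosbestic wavelengths; quantifies
    vasomotion as peak Fourier Power in the 0.03-0.06 Hz band; classifies
    capillary flow as continuous, intermittent or stopped and computes
    functional capillary density; and provides the statistical tail
    (constant-model ROUT outlier removal with matched-field exclusion,
    two-way ANOVA with Bonferroni post-hoc, group summaries and Power
    heat-map tables). A forward simulator generates capillary videos,
    spectroscopy recordings and whole cohorts with complete ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    car,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
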