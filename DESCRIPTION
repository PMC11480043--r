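Package: bodygirth
Title: Contactless Body Girth Measurement from Multi-Angle Silhouettes
Version: 0.1.0
Authors@R:
    person("Afyon", "Imaging Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates waist and hip circumferences from sets of 2D body
    silhouettes photographed at uniform angular increments around the subject.
    Images are segmented to binary silhouettes, per-row pixel widths are scaled
    to centimetres using the subject's known stature, and cross-section
    perimeters are estimated with a law-of-cosines inscribed polygon built on
    the projected half-widths, alongside the classical ellipse-circumference
    baseline. Includes a parametric superellipse body-phantom generator with an
    exact arc-length oracle for validation, percent-error and RMS-error
    reporting, longitudinal change monitoring for obesity follow-up, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    png,
    jpeg,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
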