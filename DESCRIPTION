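Package: cavesong
Title: Detection and Population-Signature Analysis of Cavefish Click Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of click-type sounds in underwater
    (hydrophone) recordings of Mexican cavefish. Implements matched-filter
    event detection with supervised threshold tuning against annotated
    ground truth, segmentation of detections into pulses and Single or
    Serial Click events, extraction of the standard acoustic parameters
    (dominant frequency, duration, signal-to-noise ratio, interpulse
    statistics), and multiparametric population-signature statistics:
    Kruskal-Wallis tests with Dunn post hoc comparisons, principal
    component acoustic spaces with confidence ellipses, permuted
    discriminant function analysis, and geography-projected hierarchical
    clustering. A seeded synthetic-soundscape generator with exact ground
    truth supports end-to-end validation without field audio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    MASS,
    ape,
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
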