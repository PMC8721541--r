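Package: loopsim
Title: In Silico Trials of Hybrid Closed-Loop Insulin Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for closed-loop in silico trials of
    do-it-yourself artificial pancreas algorithms in type 1 diabetes. Provides
    an open compartmental glucose-insulin virtual patient model with a
    reproducible three-age-group cohort generator, CGM sensor and insulin pump
    device models, an oref0-style hybrid closed-loop controller (insulin on
    board, carbs on board, autosensitivity, super micro boluses, unannounced
    meal detection), a scripted two-day meal scenario engine with hypotreatment
    rules, and the consensus glycemic-control metrics (time in ranges, LBGI,
    HBGI) aggregated per time block and across the cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
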