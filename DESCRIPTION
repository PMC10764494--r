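Package: myodetect
Title: Detection of Myoclonic Jerks from Home-Cage Video Tracking of Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects myoclonic jerks in home-cage video-tracking time series of
    mice. Implements the velocity, movement (hysteresis), mobility-state and
    multi-condition classifiers of a standard overhead video-tracking analysis
    profile, scans the resulting state traces for short velocity bursts
    (~20-60 cm/s) emerging from sustained immobility, auto-rejects voluntary
    locomotion, and pairs consecutive events 1-20 s apart. Ships a seeded
    ground-truth simulator of 4-h home-cage sessions (sleep, exploration,
    grooming, injected jerks, tracking noise), a minimal overhead blob tracker
    that turns rendered frame stacks into tracking tables, event-matching
    evaluation against ground truth, and two-way ANOVA with Sidak-adjusted
    group comparisons for cohort reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    png,
    EBImage,
    car
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
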