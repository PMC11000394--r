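Package: restalpha
Title: Resting-State EEG Alpha-Rhythm Case-Control Analysis
Version: 0.1.0
Authors@R: person("restalpha", "maintainers", email = "restalpha@example.org",
    role = c("aut", "cre"))
Description: Pipeline for case-control analysis of the resting-state EEG
    alpha rhythm. Reads and writes EDF recordings on the 25-electrode IFCN
    10-20 montage, band-pass filters and re-references to the retroauricular
    pair, selects artifact-screened 20-s epochs, estimates Welch power
    spectral density, detects the individual alpha peak frequency (IAF) and
    the mean alpha-band PSD in IAF +/- 1 Hz per electrode, and compares two
    matched groups with Kruskal-Wallis, Mann-Whitney and Benjamini-Hochberg
    false-discovery-rate statistics, plus topographic maps. Includes a
    seeded synthetic resting-EEG cohort generator (1/f background,
    narrowband alpha, posterior topography, blink artifacts) so the whole
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
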