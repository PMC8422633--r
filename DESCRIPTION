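Package: chronolam
Title: Chronobiological Analysis of Locomotor Activity Monitor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing spontaneous locomotor activity of mosquitoes
    (and other small insects) recorded with infrared beam-break activity
    monitors under light:dark (LD) and constant-darkness (DD) regimens.
    Reads and writes tab-delimited monitor files, applies standard quality
    filters (acclimation-day trimming, dead-individual detection), computes
    chi-square periodograms with rhythmicity classification and free-running
    period extraction, builds per-individual chronotype barcodes and Shannon
    diversity of period combinations, derives activity endpoints (nightly and
    hourly activity, onset of activity, dusk peak time), and performs
    group-level inference (Williams-corrected G tests, negative-binomial rate
    ratios with cluster bootstrap, period and onset contrasts). A synthetic
    actogram generator with known ground truth supports parameter-recovery
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
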