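Package: solereflex
Title: Analysis of Mechanical Foot-Sole Stimulation, Reflex EMG and Ankle
    Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models pneumatic plantar-stimulation protocols (single-pulse and
    walking-like cyclic loading of the heel and forefoot), processes surface
    EMG from the tibialis anterior and soleus to detect mechanically evoked
    reflexes with a baseline mean-plus-SD threshold and a 10 ms duration
    criterion, normalizes muscle activity to maximal-voluntary-contraction
    RMS, computes the sagittal ankle angle from knee/ankle/metatarsal marker
    coordinates, quantifies plate-induced angle changes and reflex-induced
    perturbations, and aggregates per-subject summaries into tables with
    paired one-sided t-tests. A synthetic-session generator produces EMG,
    marker and trigger series with known ground truth so the whole pipeline
    is testable without human-subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
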