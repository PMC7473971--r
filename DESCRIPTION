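Package: melofractal
Title: Melodic-Fractal Stimulus Generation and Auditory Hierarchy Experiment Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates melodic-fractal stimuli from a recursive hierarchical
    embedding rule, together with the iterative and repetition control rules
    used in auditory hierarchy-learning experiments. Builds the associated
    foil (violation) stimuli, schedules tones on a nested timing grid, and
    renders stimuli to standard MIDI and WAV files. Constructs balanced
    four-session fMRI trial designs with jittered generation phases, exports
    BIDS-style event tables, and simulates participant responses under an
    equal-variance signal-detection model, with d-prime estimation and a
    one-way repeated-measures ANOVA for behavioral analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
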