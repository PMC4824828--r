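Package: stresslab
Title: Synthesis and Simulation of Lexical-Stress Discrimination
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the perception of lexical stress
    (trochaic versus iambic two-syllable patterns) with go/no-go operant
    methods.  Provides parametric source-filter synthesis of nonsense-word
    stimuli with four controllable stress cues (pitch contour, duration,
    amplitude, vowel quality) and the eight cue-removal manipulations used
    in generalization testing; trial scheduling with species-specific
    phase criteria and reinforcement contingencies; simulated cue-weighting
    observers that generate go/no-go response logs; and the
    discrimination-ratio and binomial analyses used to score such
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
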