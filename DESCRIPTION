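Package: sleeposc
Title: Detection, Coupling and Laterality of NREM Sleep Oscillations in Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based detection of slow oscillations, delta waves and sleep
    spindles from multichannel NREM scalp EEG; temporal nesting of spindles to
    slow events; per-channel event densities, hemispheric laterality indices
    and their ratio; topographic scalp maps; and cohort statistics (paired
    t-tests, one-way ANOVA, linear mixed-effects models with effect sizes).
    Includes a seeded synthetic-EEG generator that embeds ground-truth events
    in 1/f background so every pipeline stage is testable without recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
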