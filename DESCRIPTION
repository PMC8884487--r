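Package: tonecoh
Title: Temporal-Coherence Auditory Figure-Ground Stimuli and MEG-Style Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis and validation of temporal-coherence figure-ground
    tone-cloud stimuli (ERB-spaced tone banks, band-limited stochastic
    envelopes, coherence schedules), a gammatone-filterbank periphery model
    that verifies the stimulus design, a synthetic two-group cohort generator
    emulating source-space auditory-cortex responses (evoked M1/M2
    components, late induced gamma, 1/f background, behavioral phenotypes),
    and the downstream analysis chain: event collapsing, baseline z-scoring,
    evoked window scores, multitaper spectrograms with DPSS tapers, induced
    gamma power, mixed-effects group-by-condition inference, repeated-split
    linear-SVM diagnosis classification, neural-to-behavior regression and
    age residualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
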