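Package: asrtlab
Title: Simulation and Analysis of the Alternating Serial Reaction Time Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying implicit statistical learning with the
    alternating serial reaction time (ASRT) task. Generates the task's
    probabilistic stimulus streams, classifies trials by second-order
    transitional probability (moving-window triplets), simulates cohorts of
    synthetic participants with reaction times, multichannel event-related
    potential (ERP) segments carrying a parameterised centroparietal P3
    component, and inclusion-exclusion generation runs. Provides the
    matching measurement pipelines (median reaction times, P3 peak and late
    P3 mean amplitudes after baseline correction and artifact rejection)
    and within-subject factorial ANOVA with Greenhouse-Geisser correction,
    partial eta-squared, and LSD pairwise follow-ups.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
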