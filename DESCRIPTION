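Package: memorychain
Title: Memory Chain Models of Learning, Forgetting, and Amnesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the memory chain model of systems consolidation: a
    feed-forward cascade of memory stores (e.g. hippocampus/medial temporal
    lobe to neocortex) in which trace intensity declines exponentially in each
    store while inducing traces in the next, with recall probability
    p(t) = 1 - exp(-intensity). Provides closed-form retention and Ribot
    (retrograde amnesia) curves, lesion operators and named pathology profiles
    (Korsakoff, Alzheimer, Huntington), the relative retrograde (rr) gradient
    as both a data transformation and a model curve, multi-trial intensity
    accumulation, simultaneous nonlinear least-squares fitting of control and
    lesioned retention curves with shared/fixed/free parameter structure, an
    exact event-driven trace-level simulator, and binomial synthetic-data
    generators for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
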