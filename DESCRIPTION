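Package: aafdiscrim
Title: Auditory Cortex Speech-Discrimination Metrics and Synthetic Spike-Train Generators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spike-train response metrics for multiunit auditory cortex
    recordings (driven spike counts, onset and peak latency by a
    3-SD-above-spontaneous threshold, vector strength for periodic
    noise-burst trains, frequency-intensity tuning curves), a single-trial
    PSTH nearest-neighbor classifier for pairwise speech-sound
    discrimination, go/no-go behavioral scoring (percent correct, d-prime,
    training-stage criteria), and an inhomogeneous-Poisson synthetic
    cortex generator with per-group presets modeling prenatal-VPA and
    control animals before and after speech training. Includes an
    end-to-end pipeline that generates data, computes per-site metrics,
    and reports group means with two-sample comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
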