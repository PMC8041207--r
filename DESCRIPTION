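Package: immunoclock
Title: Coupled Lung Circadian Clock and Acute Inflammation Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the mammalian lung circadian clock (a 12-variable
    transcription-translation feedback-loop model of Per, Cry, Rev-Erb, Ror
    and Bmal1) bidirectionally coupled to an 8-variable acute-inflammation
    model of endotoxemia (activated phagocytes, tissue damage and the
    cytokines TNF-alpha, IL-6 and IL-10). Provides limit-cycle and
    circadian-time analysis, timed endotoxin-challenge experiments, gene
    knockouts, chronic-jet-lag (shift-work) variants calibrated to
    sex-specific clock-gene alterations, two-step least-squares calibration
    against cytokine and clock-gene time series, Sobol' global sensitivity
    analysis, and synthetic-data generators emulating the statistical
    structure of lung clock-gene and endotoxemia cytokine measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
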