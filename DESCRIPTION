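Package: cartcrs
Title: Multi-Layer Mechanistic Modelling of CAR-T Cell Therapy and
    Macrophage-Mediated Cytokine Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation, phase and log-slope analysis, two-step
    parameter estimation, macrophage activation-source decomposition,
    counterfactual intervention scenarios, and AIC-based model-variant
    selection for a multi-layer ordinary-differential-equation model of
    chimeric antigen receptor (CAR) T-cell therapy.  The model couples
    three CAR-T phenotypes (injected, expander, persister) to
    antigen-positive and antigen-negative tumour compartments and to a
    macrophage/IL-6 layer with three activation mechanisms (DAMP release,
    antigen binding, CD40-CD40L contact).  Includes a virtual-patient
    generator emulating sparse clinical sampling schedules, unit
    conventions and detection limits, so that every pipeline stage is
    testable without clinical data.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
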