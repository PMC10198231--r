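Package: tremorMPP
Title: Motion Power Percentage Tremor Quantification and Dose-Response
    Inference for the Harmaline Mouse Model
Version: 0.1.0
Authors@R:
    person("Preclinical", "Tremor Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying drug-induced suppression of harmaline
    tremor in mice from load-sensor motion recordings. Provides a synthetic
    motion-trace generator emulating the epoch/dose/genotype structure of a
    platform tremor experiment (broadband locomotion background plus a
    9-16 Hz tremor component with Emax/Hill pharmacodynamics), Welch
    power-spectral-density estimation and the motion power percentage (MPP)
    band-power ratio statistic, repeated-measures mixed ANOVA with
    model-based means, pooled standard errors and protected Fisher-LSD
    dose-versus-vehicle comparisons, and an end-to-end
    simulate/quantify/analyze pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
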