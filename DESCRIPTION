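Package: metaflex
Title: Whole-Body Postprandial Metabolism and Insulin-Resistance Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a twelve-state dimensionless kinetic model of
    whole-body carbohydrate and fat metabolism: plasma insulin, glucose,
    triglyceride (TAG) and free fatty acids (FFA), hepatic glycogen, FFA
    and TAG, and skeletal-muscle AMP, glucose, glycogen, FFA and TAG.
    Insulin sensitivity of the hepatic, adipose and muscle pathways is
    parametrised by multiplicative sensitivity factors, so healthy and
    insulin-resistant subjects (single tissues, tissue pairs, or the whole
    body) can be compared on a common postprandial meal protocol.
    Provides fasting-state calibration, stiff and explicit integration of
    meal responses, derived observables (fractional glucose oxidation as a
    metabolic-flexibility readout, adipose TAG clearance), scenario
    summary tables, a YAML-configurable command-line driver, and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
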