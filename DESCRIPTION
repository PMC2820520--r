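Package: tcsfeedback
Title: Feedback-Sign Analysis of Autoregulated Bacterial Two-Component Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic reaction-network model of a bacterial two-component
    signaling system (sensor histidine kinase plus response regulator expressed
    from one autoregulated operon), with tools to solve steady states, integrate
    piecewise-constant signal protocols, and quantify the effective sign of the
    transcriptional feedback loop. Implements open-loop gain, exogenous
    phosphorylation flux decomposition, overshoot and response-time statistics,
    signal-interruption ("learning") experiments, induction range, signal-space
    sign maps, log-uniform Monte Carlo parameter surveys with a feasibility
    filter, and a genetic algorithm for selecting parameter sets with desired
    response characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
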