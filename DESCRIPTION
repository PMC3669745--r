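Package: fearext
Title: Exhaustive State-Space Analysis of Amygdala Fear-Extinction Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing rate-coded models of the amygdala circuitry
    underlying fear conditioning and its extinction.  Circuits are small
    feedforward networks with integer synaptic weights; plasticity is modelled
    as unit long-term potentiation (LTP) steps during conditioning and unit
    long-term depression (LTD) steps during extinction, bounded between 0 and
    2 in absolute value.  The package enumerates every distinct terminal
    weight configuration that completes extinction after conditioning,
    evaluates constraint queries over the terminal set (CB1-mediated GABAergic
    LTD of interneuron synapses, cue-response preservation, tied-weight
    equality), and cross-checks the integer enumeration with a real-valued
    derivative-free pattern search over weight-change vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    igraph,
    jsonlite,
    readr,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
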