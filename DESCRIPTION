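Package: gcshutdown
Title: Agent-Based Simulation of Germinal Center Shutdown Mechanisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic lattice-based agent simulation of the germinal center
    (GC) reaction with pluggable shutdown mechanisms: antigen consumption by
    B cells, antibody feedback (antigen masking), follicular dendritic cell
    network contraction, immune-complex cycling modulation, decaying Tfh
    signaling capacity, terminal differentiation, and exhaustion of B cell
    division capacity. Four assumption sets couple Tfh signal intensity and
    the division program to pMHC presentation. Includes diagnostic readouts
    (pMHC density, uptake success fraction, FDC network size per B cell,
    surface antigen fraction, recycling and output fractions), an
    antibody-feedback ODE module with 11 affinity bins, and the immune-power
    efficiency statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
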