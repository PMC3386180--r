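Package: psmclock
Title: Gene- and Cell-Based Simulation of the Mouse Somitogenesis Clock
Version: 0.1.0
Authors@R:
    person("PSM", "Maintainers", email = "psmclock@example.org", role = c("aut", "cre"))
Description: Simulates the growing mouse presomitic mesoderm (PSM) as a
    lattice of virtual cells, each integrating a 38-variable gene
    regulatory network built around the Hes7 negative-feedback oscillator,
    Delta/Notch juxtacrine coupling, Wnt3a/Fgf8 gradients formed by mRNA
    decay after growth-zone exit, and the Mesp2/Ripply2/Epha4 boundary
    module. Provides a reduced two-cell system for parameter scans,
    robustness sampling and calibration, declarative virtual-knockout
    experiments, trajectory analysis (period, amplitude, stripes, waves,
    beats, synchrony), and virtual in-situ staining renders.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
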