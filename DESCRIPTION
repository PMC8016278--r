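Package: AMPARtrafficking
Title: Receptor Trafficking Models of Early-Phase Long-Term Potentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A hierarchy of biophysical models of AMPA-type glutamate
    receptor (AMPAR) trafficking in dendritic spines, used to study how
    early-phase long-term potentiation (E-LTP) is maintained. Implements a
    two-pool ordinary differential equation model of mobile and
    PSD-bound receptors, its extension by structural plasticity of the
    spine (sLTP) with recycling-endosome-driven exocytosis, a stochastic
    square-lattice model of cooperative receptor binding at the
    postsynaptic density with a calibrated mean-field reduction, and the
    combination of all mechanisms. Includes LTP-induction protocols with
    and without blocked exocytosis, fluorescence-recovery (FRAP)
    simulations, lattice statistics (occupancy, coefficient of variation,
    per-slot dwell times), fixed-point continuation analyses, and random
    parameter-space sampling against reference EPSP decay curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
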