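Package: cycleswitch
Title: Kinetic Modelling and Regulatory Hypothesis Screening of the
    G0/G1-to-S Cell-Cycle Switch
Version: 1.0.0
Authors@R:
    person("cycleswitch", "developers", email = "cycleswitch@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the restriction-point switch that commits
    quiescent (G0) hematopoietic stem cells to S-phase entry.  Provides an
    eight-species ordinary-differential-equation model of the Rb-E2F
    network (active CyclinD:Cdk4/6 and CyclinE:Cdk2 complexes, E2F, Rb,
    and the CDK inhibitors p18/p19) with pluggable regulatory edges for
    the transcription factors Maff and Egr3; a stiff BDF integrator and
    damped-Newton equilibrium refinement with Jacobian-eigenvalue
    stability classification; parameter sweeps that trace bifurcation
    branches and detect bistable intervals; an exhaustive 81-way screen of
    candidate Maff/Egr3 regulatory hypotheses against qualitative
    experimental criteria; an exact-match promoter motif scanner (maf
    recognition element and the Egr3 cis element); and deterministic
    synthetic-data generators for promoter fixtures and qualitative
    reference profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    methods
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
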