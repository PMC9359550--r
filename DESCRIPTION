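Package: cfchoice
Title: Process Models of Perceptual Confidence for Confidence Forced-Choice
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and model-based analysis of confidence forced-choice
    experiments on suprathreshold spatial discrimination.  Observers judge
    whether the mean of a dot-generating distribution lies left or right of
    centre and, after every pair of judgements, report which decision they
    are more confident about.  The package simulates the full experiment
    (balanced interleaved schedules, dot-cloud stimuli, exact session
    repeats for N-pass designs), implements a Bayesian observer that infers
    the generating mean and precision jointly under a normal-gamma prior,
    and provides twelve process models of confidence spanning Probability,
    Evidence-Strength and Heuristic metrics.  Models are fit by two-step
    simulation-based maximum likelihood (brute-force grid for the perceptual
    stage, bounded derivative-free optimisation on response-conditioned
    measurement banks for the confidence stage) and compared by AICc.
    Validation tools include model-recovery confusion matrices, parameter
    recovery, and N-pass confidence-agreement analysis with model-predicted
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr,
    lhs
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
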