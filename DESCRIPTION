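Package: mousekin
Title: Kinematic Analysis of Mouse-Tracking Decision Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing computer-mouse cursor trajectories recorded
    during two-choice decision tasks (e.g. lexical decision). Derives velocity
    and acceleration profiles on a uniform time grid, detects movement onset
    and velocity/acceleration peaks, classifies discrete "change of mind"
    reversals from signed maximum deviation and double acceleration peaks,
    compares condition time-series by lagged cross-correlation, and performs
    Bayesian two-group estimation (robust t model via MCMC) alongside
    frequentist time-window tests. Includes a synthetic trajectory generator
    that produces graded-competition and change-of-mind trials for validating
    every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
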