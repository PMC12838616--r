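Package: glucontrol
Title: Hybrid Closed-Loop Insulin Dosing with Reinforcement Learning and
    Predictive Safety Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and training toolkit for fully closed-loop insulin
    delivery in type 1 diabetes. Provides a synthetic virtual patient
    (minimal-model glucose-insulin dynamics with meal disturbances and a
    noisy CGM sensor), a Kovatchev risk-index reward with cubic-spline
    hypoglycaemia smoothing, recurrent actor-critic learners (PPO, DDPG,
    SAC) over a shared LSTM state encoder, a Gaussian one-step glucose
    forecaster with a self-attention encoder, a sampling-based MPC rollout
    planner that screens candidate actions for predicted hypoglycaemia, an
    analytic safety-controller fallback, a basal-bolus clinical baseline,
    and standard glycemic evaluation metrics (TIR/TBR/TAR, LBGI/HBGI).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    deSolve
Config/testthat/edition: 3
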