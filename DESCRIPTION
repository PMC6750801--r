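Package: ptbmicro
Title: Vaginal Microbiome Dynamics and Preterm-Birth Risk Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal analyses of the vaginal microbiome in
    pregnancy cohorts with spontaneous preterm birth (PTB) and term birth (TB)
    outcomes. Implements predominant-taxon vagitype (community state type)
    assignment, low-abundance taxon filtering, soft-threshold log transforms,
    Mann-Whitney differential-abundance screening with Benjamini-Hochberg
    correction, a two-step L1-regularized logistic PTB classifier with
    leave-one-out evaluation and permutation significance, a continuous-time
    Markov chain model of vagitype transitions with an outcome covariate,
    penalized-spline mixed models of taxon trajectories over gestational age,
    sparse canonical correlation of cytokine and taxon profiles, and a
    Dirichlet-multinomial generator of synthetic longitudinal cohorts with
    recorded ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
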