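Package: torsadeRisk
Title: In Silico Proarrhythmia Risk Prediction with a Paced Ventricular
    Myocyte Model and the qNet Torsade Metric
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic assessment of drug-induced torsade-de-pointes (TdP)
    liability. Simulates a paced endocardial human ventricular cardiomyocyte
    (ORd-family electrophysiology with CiPA v1.0 conductance rescalings and a
    Markov IKr submodel with dynamic drug binding and trapping), applies drug
    effects as Hill-equation conductance block of INaL, INa and ICaL plus the
    five-parameter dynamic hERG interaction, and computes the net-charge
    metric qNet and the torsade metric score (mean qNet over 1-4x the free
    therapeutic Cmax). Measurement uncertainty is propagated by nonparametric
    bootstrap of concentration-response data into per-drug score
    distributions; proportional-odds ordinal regression derives the two risk
    thresholds; prespecified ranking (ROC1/ROC2 AUC, pairwise comparison) and
    classification (likelihood ratios, mean classification error) measures
    are estimated with resampling confidence intervals. Includes a fast
    analytic toy action-potential model and synthetic data generators so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    MASS,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'pharmacology.R'
    'modelRegistry.R'
    'cipaOrdModel.R'
    'toyModel.R'
    'fixtures.R'
    'io.R'
    'metrics.R'
    'performance.R'
    'thresholds.R'
    'pipeline.R'
    'torsadeRisk-package.R'
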