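Package: thalpop
Title: Population Analysis of Trial-Aligned Calcium Imaging in a Cross-Modal
    Go/Nogo Reversal Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-photon calcium imaging of neuronal
    populations recorded during a cross-modal (auditory/visual) Go/Nogo
    reversal-learning task: behavioural performance (d-prime, learning-phase
    detection, anticipatory licking, pupil geometry), fluorescence trace
    conditioning and trial epoching, a two-step stimulus-responsiveness
    classifier, PCA plus cosine k-means functional clustering,
    trial-by-trial population-vector correlation with linear mixed-model
    phase comparisons, weighted co-activity network metrics (hubness,
    inverse-correlation geodesics, triad clustering coefficient) with
    bootstrap deltas and removal shuffles, off-task sensory-mapping
    analyses including a multisensory integration index, and linear SVM
    population decoding with circular-permutation chance estimation.
    A synthetic-data generator reproduces the task's trial structure and
    planted functional cell classes so every stage can be exercised with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    lmerTest,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    pracma,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
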