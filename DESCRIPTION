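Package: gazesim
Title: Probabilistic Simulation of Visual Attention to Talking Faces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates gaze trajectories over the areas of interest (eyes,
    mouth, rest of face, elsewhere) of a talking face with a Bayesian model
    that fuses bottom-up saliency (static center-surround contrast and
    frame-difference motion, mixed by a weight theta), top-down anticipatory
    task knowledge (learning strength beta, anticipation speed gamma), and a
    selection-history memory whose belief over recently visited zones is
    inverted so that recently visited zones become less attractive. Includes
    tools to compute proportion-of-total-looking-time summaries, Eyes-Mouth
    preference scores with baseline correction, learning-curve regression
    endpoints, and a grid search that fits the three free parameters to
    looking-time data by minimising the mean squared error between simulated
    and observed regression endpoints. A synthetic-stimulus generator
    provides schematic talking-face frames and model-generated gaze datasets
    so that the full pipeline runs without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    optparse,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
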