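Package: gaitcomplexity
Title: Complexity Measures for Multi-Joint Gait Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying the complexity of locomotion
    from multi-joint kinematic time series. Implements three families of
    measures used in gait analysis: dimensionality (the number of principal
    components explaining 95% of variance, N95), variability (generalized
    variance of the joint-angle cloud and GaitSD stride-to-stride waveform
    variability on 101-point time-normalized gait cycles), and nonlinear
    dynamics (delay embedding parameterized by average mutual information
    and global false nearest neighbors, the Rosenstein largest Lyapunov
    exponent, and composite multiscale sample entropy with its Complexity
    Index). Includes a synthetic multi-joint gait generator with
    controllable latent rank, variance scale, stride noise and timing
    jitter, plus canonical benchmark signals (sine, white and pink noise,
    logistic map, Lorenz system) so every estimator is verifiable against
    analytic or ground-truth values without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    MASS,
    deSolve,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
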