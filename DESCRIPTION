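Package: mobilekin
Title: Kinematics, Clustering and Dynamical Modelling for the Infant Mobile Paradigm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for mobile-paradigm experiments in which a young
    infant's wrist is tethered to an overhead mobile and four-limb 3D motion
    capture records how spontaneous movements turn into instrumental ones.
    Provides sliding-window kinematics (instantaneous 3D speed, displacement
    rate, baseline ratio, 2-min block summaries), K-means clustering of
    multivariate learning curves, a van der Pol-Duffing limb oscillator
    coupled to a damped mobile oscillator with slow sensorimotor feedback,
    grid-search fitting of the oscillator's natural frequency to cluster-mean
    learning curves, mixed-design ANOVA with partial eta squared confidence
    intervals and Tukey HSD post-hoc tests, and a seedable synthetic-cohort
    generator for end-to-end testing without motion-capture recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
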