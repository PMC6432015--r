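Package: knotbridge
Title: Conditioned Langevin Dynamics and Knotting Pathways of Semiflexible Gaussian Rings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact Brownian-bridge (conditioned overdamped Langevin) dynamics for
    semiflexible Gaussian ring polymers between two prescribed conformations in a
    fixed time, including conditioning on the set of circular permutations of the
    target ring. The quadratic chain model is propagated in Fourier (Rouse) mode
    space where every mode obeys an independent Ornstein-Uhlenbeck bridge. A
    topology-analysis layer identifies knot types from Alexander determinants
    evaluated with exact integer (modular) arithmetic, and computes writhe and
    average crossing number from random projections or the exact Gauss integral.
    Endpoint conformations of prescribed knot type are generated by parametric
    initializers and equilibrated by crankshaft Monte Carlo of self-avoiding
    cylinder rings. A pathways layer assembles bridge runs into per-frame reports
    (RMSD, knot bands, writhe, crossing numbers) and ensemble statistics of
    knotting-unknotting routes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
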