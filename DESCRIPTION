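Package: sacwaves
Title: Stochastic Simulation and Event Analysis of Cholinergic Retinal Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Conductance-based stochastic model of starburst amacrine cells
    (SACs), the cells that generate stage II cholinergic retinal waves. A
    Morris-Lecar-type spiking core is extended with Hodgkin-Huxley sodium
    gating, calcium-driven cAMP decay disinhibiting TREK1 potassium channels
    (the slow afterhyperpolarization), Ornstein-Uhlenbeck channel noise, and
    reciprocal acetylcholine/GABA release coupling cells on a 2D lattice
    through anisotropic diffusion. Includes equilibrium and saddle-node
    bifurcation analysis of the reduced spiking subsystem, a spike/burst
    quantification pipeline (mean + 4 SD thresholding, max-interval burst
    sorting), 3D spatiotemporal wave segmentation, and a +10 percent
    parameter-gradient sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
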