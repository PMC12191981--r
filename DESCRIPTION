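Package: pathmeasure
Title: Discrete-Time Brownian Dynamics and Path-Measure Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates overdamped Langevin (Brownian) dynamics in one
    dimension with the explicit Euler-Maruyama scheme and provides a toolkit
    for comparing the path measures of two diffusion processes. Implements
    the bijective noise-history map between processes driven by a shared
    thermal reservoir (the common-noise construction, under which the
    change of measure is unity and the Kullback-Leibler divergence
    vanishes) and the Girsanov-type common-path construction, whose KL
    divergence is estimated by Monte Carlo and checked against closed forms
    for constant drift, Ornstein-Uhlenbeck, and bridge processes. Evaluates
    the discrete Onsager-Machlup functional, its drift-dependent J part and
    continuous-time limit, the Ito-Girsanov action with its path potential,
    and the quadratic variation on simulated paths. Includes exact Brownian
    and Ornstein-Uhlenbeck bridge samplers, residence-time free-energy
    estimation on double-well potentials with a Boltzmann quadrature
    reference, and spectral diagnostics of the drift independence of
    high-frequency path components.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
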