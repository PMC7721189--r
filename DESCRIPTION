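Package: spatscale
Title: Urban Scaling Laws with Spatial Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling of urban scaling laws y ~ x^beta that accounts
    for spatial interactions between urban units. Token counts (GDP, deaths,
    infrastructure) are allocated to cities by a multinomial model whose
    per-capita attachment probability depends on a distance-decay interaction
    kernel (city-only, gravitational/Lorentzian, or exponential). Provides
    maximum a posteriori estimation of the scaling exponent and the interaction
    range, parametric-bootstrap uncertainties, Bayesian model comparison via
    description length computed by numerical integration of the marginal
    likelihood, the conventional log-log least-squares fit for comparison, and
    a seeded generator of synthetic spatially embedded city systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
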