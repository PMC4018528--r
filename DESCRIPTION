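Package: capinit
Title: Minimal Kinetic Model of Cap-Dependent Translation Initiation at
    Fertilization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action kinetic model of the eIF4E/4E-BP/eIF4G network that
    controls cap-dependent translation initiation in the sea urchin egg.
    Provides the six-species ordinary differential equation system with
    linearly ramped rate constants, coupled binding-equilibrium and
    flux-balance steady-state solvers, least-squares and grid-search
    parameter learning from total 4E-BP time courses, fertilization and
    rapamycin scenario simulations, surface plasmon resonance 1:1 Langmuir
    sensorgram simulation and global kinetic fitting, and seeded synthetic
    data generators emulating immunoblot densitometry measurements.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
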