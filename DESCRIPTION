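Package: crossmigrate
Title: Cross-Mass Transfer and Migration Modelling for Multilayer Packaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the migration of chemicals (monomers, additives,
    non-intentionally added substances) through stacks of polymer, air and
    liquid layers over multi-step storage-and-use scenarios, as encountered
    in pharmaceutical single-use systems and food packaging. Provides
    Flory-Huggins/Henry sorption thermodynamics with analytic uniform-activity
    equilibria, a one-dimensional finite-volume diffusion solver with
    local-thermodynamic-equilibrium interface coupling and Robin (mass Biot
    number) boundary conditions, layer resistance diagnostics, Fuller-law gas
    diffusivities, a Weibull contact-time probabilistic exposure layer, and
    identification of unknown partition coefficients from desorption kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
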