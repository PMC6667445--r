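Package: stomsafe
Title: Stomatal Safety-Efficiency Trade-Off Analysis
Version: 0.1.0
Authors@R:
    person("Plant", "Ecophys Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the trade-off between maximum stomatal
    conductance (g_max) and the sensitivity of stomatal closure to leaf
    dehydration (Psi_gs50). Fits stomatal-conductance versus leaf-water-potential
    response curves by maximum likelihood with AICc model selection among four
    candidate function families, applies artifact-refinement filters, derives
    g_max and the water potentials at 20/50/80 percent stomatal closure, computes
    the anatomical maximum stomatal conductance from stomatal density and
    geometry, simulates a steady-state soil-plant-atmosphere hydraulic model
    coupled to stomatal closure and carboxylation-limited photosynthesis over a
    g_max x Psi_gs50 grid, and runs ahistorical (Pearson, standard major axis)
    and phylogenetic (PGLS under Brownian motion, Pagel's lambda, and
    Ornstein-Uhlenbeck) trait-correlation analyses. Includes a seeded
    synthetic-data generator emulating the statistical structure of dehydration
    experiments so the full pipeline is testable without measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
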