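Package: citflux
Title: Constraint-Based Flux Analysis for a Citric-Acid-Producing Fungus
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, curating and simulating genome-scale
    metabolic models of filamentous fungi, motivated by citric-acid
    fermentation in Aspergillus tubingensis. Reads and writes models in
    SBML (Level 3 with the 'fbc' extension) and a hand-editable tabular
    dialect; parses Boolean gene-protein-reaction rules; reports
    per-compartment model statistics; detects and prunes dead-end
    metabolites, generic reactions and blocked reactions; converts
    measured macromolecular biomass composition into a biomass objective;
    performs flux balance analysis, flux variability analysis, gene
    deletions and Biolog-style carbon-source phenotype simulation with a
    built-in bounded-variable simplex solver; and runs dynamic FBA of a
    glucose-xylose fermentation with Michaelis-Menten uptake kinetics,
    glucose-threshold xylose repression, low-affinity glucose transport,
    non-growth-associated maintenance and phosphate drawdown. Includes a
    seeded synthetic-data generator producing a compartmentalised toy
    model, phenotype fixtures and noisy fermentation trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
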