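Package: mdftools
Title: Max-Min Driving Force Analysis of Metabolic Pathways
Version: 0.1.0
Authors@R:
    person("MDF", "Tools Developers", email = "mdftools@example.org",
           role = c("aut", "cre"))
Description: Thermodynamic profiling of metabolic pathways via the Max-min
    Driving Force (MDF) framework. Given reaction stoichiometries (actual
    molecularities, net-flux direction convention) and standard transformed
    Gibbs reaction energies, the package finds metabolite concentrations that
    maximize the smallest reaction driving force by linear programming,
    reports the MDF, per-reaction flux-force efficacies, and reaction and
    metabolite shadow prices from the dual solution, and compares pathway
    variants by MDF versus ATP yield (Pareto fronts, pH sweeps). Includes a
    self-contained dense simplex LP solver with dual extraction, readers for
    YAML and TSV pathway files, a command-line interface, and deterministic
    fixture generators with closed-form oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
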