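Package: mitoflux
Title: Constraint-Based Analysis of Enterocyte Mitochondrial Metabolism Under Dietary Lipid Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based modelling of small-intestinal enterocyte
    mitochondrial metabolism under diets differing in lipid type and lipid load.
    Provides a compartmentalized metabolic network representation with JSON, SBML
    (Level 3 FBC) and tabular input/output, a reduced but fully elementally
    balanced enterocyte mitochondrial network with analytic fatty-acid
    beta-oxidation stoichiometry, conversion of printed diet compositions into
    exchange-reaction uptake bounds, flux balance analysis with maximal ATP
    production as objective, artificial centering hit-and-run (ACHR) sampling of
    the steady-state flux polytope, and per-reaction cross-diet statistics
    (one-way ANOVA with Tukey-Kramer post hoc comparisons and compact letter
    displays), orchestrated as a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
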