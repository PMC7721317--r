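Package: dielfba
Title: Time-Resolved, Environment-Coupled Diel Flux Balance Analysis of Leaf Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modelling of leaf metabolism over the diel
    (24-hour) cycle. Builds a cyclic time-expanded flux-balance model from a
    compartmented plant core network by concatenating per-hour copies joined
    by storage "linker" reactions (starch in the plastid; sugars, carboxylic
    acids, amino acids and nitrate in the vacuole), couples metabolic CO2
    demand to transpirational water loss through a linearized stomatal
    diffusion model driven by diel temperature, humidity and light curves,
    and solves a lexicographic objective stack (maximize phloem output,
    minimize water loss at fixed output, minimize the quadratic flux sum).
    Includes Pareto productivity/water trade-off scans, scenario variants
    for vacuolar storage capacity (C3, CAM, unlimited) and mitochondrial
    isocitrate dehydrogenase reversibility, environment grid scans with
    water-saving metrics, CO2/ATP budget reporting, storage (linker)
    profiles and CAM phase detection. Ships a reduced synthetic plant core
    network so the full pipeline runs without external model files, plus a
    minimal SBML reader/writer and a sparse interior-point LP/QP solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    pracma
Config/testthat/edition: 3
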