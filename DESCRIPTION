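Package: tracheoflux
Title: Branching Geometry and CO2 Transport in Ant Tracheal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the branching geometry of insect tracheal
    systems and its consequences for respiratory gas exchange. Estimates the
    branching exponent relating parent to child tracheal radii by
    root-finding, tests area-decreasing against area-preserving (Da Vinci)
    and area-increasing (Murray) branching with origin-forced ordinary
    least squares and Major Axis (Model II) regression including a species
    random-intercept check, and models steady-state CO2 diffusion with
    distributed tissue influx, air sacs, and periodic convective
    ventilation in a five-level bifurcating model tracheal network. A
    seeded synthetic-morphometry generator reproduces the statistical
    structure of per-branch radius measurement tables for pipeline testing
    and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
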