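Package: pollutiongame
Title: Spatial Pollution Games with Costly Mobility on Periodic Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulator of a spatial social dilemma of pollution.
    Cooperators (cleaners) pay a fee to remove pollution from their
    neighbourhood while defectors (polluters) gain a benefit and spread
    pollution with a long-range inverse-square kernel on a doubly periodic
    square lattice. Agents relocate by minimizing felt pollution plus a
    per-unit-distance mobility cost and imitate the nearest neighbour with
    the lowest total expense. Includes homogeneous, two-group heterogeneous
    and strategy-dependent mobility-cost schemes, per-step lattice metrics
    (cooperator fraction, per-capita pollution change, clustering,
    minority-cooperator fraction), seeded ensemble runners and parameter
    sweeps, and closed-form small-population movement analytics that serve
    as an independent oracle for the simulation engine.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
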