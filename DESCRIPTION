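Package: pathcover
Title: Minimum Path Covers of DAGs with Subpath and Paired-End Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solvers for the family of minimum path cover (MPC) problems on
    directed acyclic graphs that arise in transcript multi-assembly from
    RNA-Seq splicing graphs. Implements classical and minimum-weight MPC via
    min-flow with lower bounds, MPC with subpath constraints (long reads or
    transfrags) via a constraint-merging reduction to classical MPC, its
    weighted variant via min-cost circulation with flow lower bounds, and MPC
    with paired subpath constraints (paired-end reads) via exact coloring of a
    constraint incompatibility graph, which is fixed-parameter tractable in
    the number of constraints. Ships independent brute-force oracles, a
    synthetic splicing-graph simulator with long-read and paired-end
    constraint samplers, an NP-hardness gadget generator, and a command-line
    interface over a JSON instance format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
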