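Package: netvenn
Title: Compare Differential-Gene Lists as a Force-Directed Experiment-Gene Graph
Version: 0.1.0
Authors@R: person("netvenn", "developers", role = c("aut", "cre"),
    email = "netvenn@example.org")
Description: Compares 2-8 differential-expression gene lists (gene id plus a
    regulation code, 1 = up, 2 = down) as a bipartite experiment-gene graph
    with a seeded force-directed layout, generalizing the Venn diagram while
    keeping per-gene regulation direction visible (concordant up, concordant
    down, or discordant across experiments).  Any gene selection can be tested
    for pathway and GO term over-representation with a one-sided Fisher exact
    test or its conservative EASE variant, against annotation tables supplied
    as GMT or long TSV files.  Graphs can be subset to the genes of a term,
    genes of interest can be highlighted as square nodes, and results export
    to deterministic SVG, PNG, graph JSON and tab-separated information
    tables.  A synthetic-fixture generator with known region structure and a
    planted enriched term makes the whole pipeline testable offline, and a
    command-line interface wires the steps together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
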