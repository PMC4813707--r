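Package: bnpcp
Title: Protein Correlation Profiling of Blue Native PAGE Complexomes
Version: 0.1.0
Authors@R:
    person("bnpcp", "maintainers", email = "bnpcp@example.org", role = c("aut", "cre"))
Description: Analysis of affinity-purified protein complexes separated by blue
    native polyacrylamide gel electrophoresis (BN-PAGE) and quantified by mass
    spectrometry fraction-by-fraction. Builds normalized migration profiles from
    MaxQuant-style per-fraction quantitation tables, clusters proteins by
    Manhattan distance with average linkage, detects bait peaks to define
    complex entities, classifies bait-normalized iBAQ stoichiometry trends by
    windowed linear regression, and computes target-gene co-occupancy overlaps
    and three-way Venn partitions. Includes a ground-truthed synthetic-data
    generator emulating a two-assembly complexome separation so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
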