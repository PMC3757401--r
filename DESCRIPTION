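Package: mcrbcarray
Title: Simulation and Domain-Level Analysis of McrBC-Array Methylome Profiling
Version: 0.1.0
Authors@R: person("Methylome", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse methylome-domain profiling by
    McrBC digestion and array-CGH readout. Generates synthetic genomes with
    megabase-scale hypomethylated domains placed in CpG-poor, gene-poor
    regions; performs in-silico McrBC digestion with gel-style size
    selection; derives two-channel probe signals and fold-change / log2
    ratios; calls hypo- and hypermethylated domains by fold-change
    thresholds; computes 50 kb CpG-density tracks; validates domain calls by
    in-silico bisulfite conversion and per-CpG methylation calling; detects
    en-bloc differential methylation changes between conditions; and
    correlates histone-mark landscapes (H3K9Ac, H3K27Me3) with gene
    expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
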