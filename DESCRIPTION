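Package: estuarch
Title: Community Assembly and Cross-Domain Co-Occurrence Analysis of
    Estuarine Planktonic Archaea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream community-ecology toolkit for multi-estuary amplicon
    surveys of planktonic archaea. Provides feature-table preparation
    (low-depth sample dropping, abundance/prevalence filtering, rarefaction,
    cumulative sum scaling), Sloan neutral community model fitting with
    migration-rate estimation and a 95 percent prediction envelope,
    distance-based community statistics (Bray-Curtis, principal coordinate
    analysis, multi-factor PERMANOVA with interactions, Mantel and partial
    Mantel tests, Spearman environmental screens), and constraint-based
    direct co-occurrence network inference over taxa and environmental
    covariates with module detection, Zi/Pi topological roles, and
    cross-domain edge summaries. A synthetic-data generator emulates the
    multi-estuary sampling design (neutral metacommunity sampling, planted
    selection, planted sparse association graphs) so every analysis can be
    exercised and validated without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    minpack.lm,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
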