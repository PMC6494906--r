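Package: pentalayout
Title: Multi-Level Transcriptional Organization of GABA-A Receptor Subunit Panels
Version: 0.1.0
Authors@R: person("pentalayout", "maintainers", email = "maintainers@pentalayout.org", role = c("aut", "cre"))
Description: Analysis pipeline for the 19-gene GABA-A receptor subunit panel
    across bulk microarray, bulk RNA-Seq and single-nucleus RNA-Seq data:
    representative-probe selection, age correction, proportional-contribution
    (compositional) normalization, regional fold enrichment and expression-profile
    classification; Ward, quantum and spectral co-clustering with a parameter-sweep
    co-occurrence consensus; 2:2:1 stoichiometric gating of nuclei and cross-level
    pairwise correlation consensus; and a Euclidean pairwise-distance
    "organizational layout" stereotypy metric with ANOVA/Dunnett comparisons.
    Ships a synthetic-data generator with planted ground truth so every stage is
    testable without downloading the public atlas resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
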