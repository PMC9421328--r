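Package: inkaflow
Title: Inferred Kinase Activity and Phosphosite Signature Analysis for
    Label-Free Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis chain for inferring differential kinase
    activity from label-free phosphoproteomic site tables. Reads
    MaxQuant-style Phospho (STY)Sites tables, applies class-I localization
    filtering and dataset-specific normalization, performs empirical-Bayes
    moderated two-group testing, computes four-component INKA kinase
    activity scores with group aggregation and hybrid pY+pSTY combination,
    builds kinase-substrate networks, and runs phosphosite-signature
    enrichment on a signed rank-value statistic. Includes a synthetic-data
    generator that plants hyperactive kinases so the whole chain is testable
    without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
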