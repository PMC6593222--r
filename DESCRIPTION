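Package: biomdex
Title: Indexed Search and Retrieval over Microbiome Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An indexed store over BIOM feature tables and sample metadata
    for cross-study sample discovery: which samples contain an exact
    sequence feature, carry a taxon, or match a metadata constraint. Data
    are partitioned by processing protocol into named contexts; feature,
    taxonomy and Porter-stemmed metadata indices are maintained over a
    small key-value storage contract with set algebra, and any query
    result can be materialized back into a BIOM table plus a metadata file
    for meta-analysis. Includes a seeded synthetic-corpus generator and a
    scaled-down pH meta-analysis demonstration pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    biomformat,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
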