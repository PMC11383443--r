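Package: bricktools
Title: A Package Manager for Versioned Life-Science Data Assets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-addressed caching, versioned installation and
    dependency management for 'bricks' -- git-style repositories that
    package extract-transform-load pipelines together with the tabular
    data artifacts (Parquet, SQLite, HDT) they build.  Provides a
    lockfile-driven incremental pipeline runner that re-executes a stage
    only when its command, dependencies or outputs change, a pluggable
    registry backend with an offline local-directory reference
    implementation, a harmonizer that reduces heterogeneous
    chemical-activity sources to the three-table
    substances/properties/activities schema, seeded fixture generators so
    the whole protocol is testable without a network, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    arrow,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
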