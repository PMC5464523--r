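Package: datawatch
Title: Detect Overdue Public Release of Datasets Cited in the Literature
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines full-text article corpora for dataset accession numbers
    (e.g., GEO series 'GSE' and SRA experiment 'SRX' identifiers), checks a
    local release-index snapshot to avoid unnecessary web queries, probes
    repository status pages through a pluggable transport, and classifies each
    cited dataset as released, overdue (cited in a published article but still
    private), invalid, or unknown. Includes analytics for overdue-count time
    series, submission-to-release delay statistics, and detection precision,
    plus a seeded synthetic-fixture generator with ground truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    DBI,
    RSQLite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
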