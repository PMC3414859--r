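Package: searcheval
Title: Evaluation of PubMed Search Strategies Against Systematic-Review
    Gold Standards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build PICO-structured Boolean queries in the PubMed
    dialect, enumerate a grid of fifteen point-of-care search strategies
    (PIC/PICO queries, Clinical Queries therapy filters, search limits,
    related-articles seeds), and score ranked search outputs against the
    trials included in systematic reviews.  Computes sensitivity (recall),
    positive predictive value (precision) and number needed to read at a
    screening cutoff or over the full output, cumulative recall curves,
    per-strategy median/IQR summaries, and paired Wilcoxon signed-rank
    comparisons between strategies.  Includes a seeded simulator of
    gold standards and ranked outputs so the whole pipeline can be
    exercised without network access, plus a packaged transcription of a
    published 30-question benchmark for worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
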