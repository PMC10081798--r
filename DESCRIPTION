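Package: ngramtrends
Title: Construct Word-Frequency Trend Analysis for Google Books Ngram Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds normalized composite word-frequency indices for
    psychological constructs (for example anxiety, depression and
    digitalization, with a religion control list) from per-word yearly
    Google Books Ngram frequencies across multiple language corpora.
    Provides curated word-list (lexicon) handling with inclusion flags,
    ingestion of Ngram Viewer JSON exports and raw ngram count files,
    most-common-word corpus-influx adjustment, per-word z-transformation
    and list aggregation, cross-language pooling, Pearson trend
    correlation matrices with significance stars, and five-year rolling
    mean stationarity diagnostics.  A seeded synthetic panel generator
    with known ground truth (trends, shared latent factor, corpus
    inflation) makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
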