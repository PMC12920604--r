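Package: pedsleepnlp
Title: Rule-Based Identification of Pediatric Sleep Mentions in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying pediatric sleep-related mentions in
    plain-text clinical notes with a two-tier keyword and regular-expression
    vocabulary. Ships a canonical transcription of the Davenport-Sirrianni
    Expanded (DSE) pediatric sleep keyword bank, compiles it into a
    whole-word multi-pattern token-trie matcher, applies the note-level
    identification rule (positive if at least one tier-1 mention is found),
    and computes note-level precision/recall/F1, span-level keyword coverage
    by sleep dimension, and Cohen's kappa. Includes a seeded generator of
    synthetic well-child-visit notes with gold labels and standoff
    annotation spans, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
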