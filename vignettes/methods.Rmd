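---
title: "Methods: matching, classification, and evaluation of pediatric sleep mentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matching, classification, and evaluation of pediatric sleep mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedsleepnlp)
```

## The identification problem

Pediatric sleep-related information appears in clinical notes in technical,
abbreviated and colloquial forms, across many note types. The package
implements the cheapest member of the NLP toolchain for this problem: a
keyword/regular-expression vocabulary applied as a note-level filter. The
output is a binary per-note decision — *does this note contain at least one
pediatric sleep-related mention?* — plus the full list of matched spans, so
that downstream components (manual review, contextual models) only need to
process the flagged notes.

The approach deliberately trades precision for recall and transparency: it
performs no negation handling, no speculation or family-history detection,
and no word-sense disambiguation. "Patient doesn't snore often" is flagged.
This is the intended division of labor — contextual validity is a
downstream concern — and the synthetic corpus generator (below) encodes
exactly this failure mode so it stays measurable.

## The two-tier vocabulary

The packaged bank (`load_vocabulary("dse")`, asset version `table2-v1`)
contains 37 high-level categories: 30 tier-1 categories used by the
identification rule, and 7 tier-2 categories (wheezing, hyperactivity,
dizziness, daytime mood, tension, inattention, nighttime anxiety) that are
matched and reported but never trigger a positive label, because in
pediatric notes they frequently describe asthma, ADHD or mood rather than
sleep. Counting entries gives 354 literal phrases and 6 regex patterns; the
bank's historically quoted size of 359 words depends on how in-table
duplicates and patterns are counted, so the package reports its own exact
counts (`vocab_stats()`) and does not enforce the quoted figure.

The transcription is verbatim by design. Apparent misspellings ("bendryl",
"trazadone", "waking up a night") are kept: clinical notes contain exactly
these misspellings, and a "fixed" bank would be a different bank. The
validator (`validate_vocabulary()`) surfaces them as findings rather than
errors: within-category duplicate surfaces are warnings (matching no-ops,
de-duplicated at compile time), cross-category shared surfaces ("trouble
sleeping" sits under both *Sleep quality* and *Sleep disturbances*) are
informational — a hit reports both categories. The one normalization
applied to the source is in the regex column, where typeset spacing inside
quantifiers (`\d + hours`) is restored to the evidently intended
`\d+ hours`; the spaced form would match no text of interest.

## Normalization and matching semantics

`normalize_text()` lowercases (ASCII case folding), folds typographic
apostrophes, quotes and dashes to ASCII one-for-one (offsets never move),
and treats every maximal run of non-alphanumeric characters as a token
boundary. Consequences worth stating:

* matching is whole-word: "nap" cannot fire inside "naproxen", "osa" only
  as a standalone token;
* hyphenation and apostrophe variants collapse: "low-energy" ≡ "low
  energy", "can’t sleep" ≡ "can't sleep" (both tokenize to `can t sleep`),
  while "cant sleep" remains distinct (`cant` is one token) — the bank
  carries the frequent dialects explicitly;
* every token records its half-open `[start, end)` interval in the raw
  text (0-based), so all reported spans are exact raw-coordinate slices.

Literal matching uses a token trie scanned greedily: at each position the
longest entry starting there wins, the scan resumes after it, and nested or
overlapping literal hits are thereby resolved longest-leftmost and
non-overlapping. This mirrors the default behavior of trie-based keyword
extractors in the Aho–Corasick family and prevents double-counting
("difficulty falling asleep" ⊃ "falling asleep"). Regex entries run on the
space-joined token string, wrapped in token-boundary lookarounds, so `\d+`
can only consume one all-digit token and `\w+` one token; regex hits are
*not* suppressed by overlapping literal hits — classification only needs
existence, and coverage analysis benefits from completeness. Whether the
original system ran its regexes on raw or preprocessed text is not
documented; token-stream semantics were adopted for consistency with
literal matching, and the package treats that as its contract.

Correctness is established structurally: `find_matches_bruteforce()` scans
every entry independently (per-entry token comparison, fixed-length token
windows for patterns) and applies the same resolution rule; the test suite
asserts exact agreement with the trie route on seeded random corpora
(200 texts in the module tests, 1000 in the end-to-end suite), plus the
invariant that every literal match's normalized text equals its entry's
token sequence.

## Classification rule

`classify_note()` labels a note positive iff it has at least one match
carrying a tier-1 category. A surface belonging to both a tier-1 and a
tier-2 category (impossible in the packaged bank, possible in user banks)
counts as tier-1: the rule keys on tier-1 presence. Two invariances are
tested: the label never depends on unmatched filler text, and deleting all
tier-2 categories changes no label.

## Evaluation conventions

* **Metrics.** precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their
  harmonic mean. Zero denominators yield `NA` ("undefined"), never a
  silent 0 — silent zeros corrupt comparisons. Values are stored at full
  precision; display rounding is 3 decimals for metrics and 1 decimal for
  percentages, half away from zero (`round_half_up()`), matching the
  conventions of published confusion tables. Recall differences are
  reported in percentage points from the unrounded recalls.
* **Span coverage.** An annotation "contains a keyword" iff at least one
  tier-1 match interval lies fully inside the annotation interval
  (`mode = "containment"`). Containment is the strictest reading —
  annotations are word- to sentence-scale, and partial overlap at a span
  edge should earn no credit; an any-overlap mode is available behind the
  `mode` flag for sensitivity analysis. Tier-2 matches never count toward
  coverage. Per dimension the most-present keyword is the entry surface
  occurring inside the largest number of that dimension's annotations
  (counted once per annotation; ties broken lexicographically). A
  dimension with zero annotations reports `NA`, not a division error.
* **Cohen's kappa.** κ = (p₀ − pₑ)/(1 − pₑ) with pₑ from the two
  labelings' marginal frequencies; the degenerate pₑ = 1 case (both raters
  constant and identical) returns 1.

## The synthetic corpus generator

Real pediatric notes cannot be shared, so `generate_corpus()` fabricates
well-child-visit-style notes from fixed sentence templates (HPI/ROS/plan
register, no external text resources) with gold note labels and gold
standoff spans at exact offsets. What it emulates:

* **positive notes** carry 1–3 mentions, each either a template embedding a
  verbatim tier-1 surface, or a keyword-free paraphrase ("Teacher notes he
  nods off during afternoon lessons") that a human annotator would tag but
  the matcher cannot hit — the mechanism behind span coverage sitting near
  three-quarters rather than 100%;
* **negative notes** optionally carry negated sleep phrases ("Denies
  snoring or apnea at this time") that drive false positives, and
  tier-2-only sentences ("Mild wheezing noted on lung exam") that must not
  flip the prediction.

Every paraphrase and filler template is verified *at generation time* to
produce zero matches, negation templates to contain a tier-1 surface, and
tier-2 templates to contain tier-2 but no tier-1 — so the generator's
guarantees hold by construction, not by hope. A single RNG stream is
consumed in documented order (per note: the positive/negative draw, then
mention and sentence draws left to right), making corpora byte-identical
under a fixed seed.

Defaults are fixed to the package's reference study conditions: 300 notes
at prevalence 244/300; per-dimension mention weights proportional to the
annotated per-dimension span totals (behavior 96, satisfaction 124,
alertness 143, timing 87, efficiency 164, duration 40, medication 199,
disorder 204, intervention 99); keyword-free mention rate 0.228 (one minus
the 77.2% overall span coverage); negation-distractor rate 0.75 (42 of 56
mention-free notes being falsely flagged). Mentions-per-note (1–3) and the
tier-2-only rate (0.25) have no documented empirical counterpart; they were
chosen once as plausible for screening-heavy well-child documentation and
are not tuned thereafter.

What the generator does **not** emulate: real EHR templates and section
headers, department and demographic mix, misspellings in note text,
mention-density correlation with diagnosis, and free-text variability
beyond the fixed template pools. A perfect score on synthetic data
therefore demonstrates the mechanics of matching, classification and
scoring — not clinical-grade performance; on real notes the keyword-free
and negated forms are more varied than any template pool.

## Numerical and degenerate-input choices

* Character offsets 0-based half-open everywhere (in memory and in JSONL);
  token indices 1-based in the R API.
* Empty text → empty token list → negative classification; empty corpus →
  empty (but valid) outputs; a vocabulary file with zero categories is an
  error, not an empty vocabulary.
* `round_half_up()` adds a 1e-9 guard before flooring so that values whose
  binary representation falls a hair under x.5 still round up; values
  genuinely within 1e-9 of a boundary are indistinguishable at the
  precision reported.
* Matcher compilation is a pure function of the vocabulary; the CLI's only
  randomness is `generate --seed`.

## Problem sizes in the test suite

The suite exercises: 200 random strings for offset-fidelity properties,
200 + 1000 random texts for trie/oracle equivalence, corpora of 40–2000
synthetic notes for determinism, prevalence calibration (exact binomial
99% band at n = 2000) and end-to-end recall (exact recovery at n = 500
with confounders off; binomial band around 0.75 at keyword-free rate 0.25
with one mention per note). These sizes keep the full suite in the
low minutes on a single core while leaving the binomial checks
well-powered.

## Known limitations

* No contextual filtering: negation, speculation and non-patient mentions
  are matched and counted, by design.
* The regex oracle route covers space-separated token-element patterns
  (all six packaged patterns); exotic user regexes are matched by the main
  route but outside the oracle's scope.
* Coverage statistics depend on annotation-span granularity: sentence-level
  spans absorb more matches under containment than word-level spans;
  the any-overlap mode bounds that sensitivity from above.
* The vocabulary reflects one institution's documentation dialect;
  applying it elsewhere likely requires re-validation and possibly new
  tier-2 demotions.
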