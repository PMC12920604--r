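# pedsleepnlp

Rule-based identification of pediatric sleep-related mentions in clinical
notes.

Sleep problems in children are routinely under-detected in primary care:
mentions are scattered across note types and expressed in everything from
formal terminology ("obstructive sleep apnea") through abbreviations ("osa")
to parent language ("trouble breathing while asleep"). Deep models that
resolve such variability are expensive to run over millions of notes;
a keyword first pass is not. `pedsleepnlp` implements such a first pass for
pediatric sleep health, for health-informatics teams who need a transparent,
low-resource filter in front of manual review or heavier NLP.

## What it does

* **Two-tier keyword bank.** Ships a canonical transcription of the
  Davenport–Sirrianni Expanded (DSE) pediatric sleep vocabulary: 37
  high-level categories (354 literal phrases plus 6 regular-expression
  patterns). The 30 tier-1 categories drive note identification; the 7
  tier-2 categories (e.g. *Wheezing*, *Inattention*) are matched and
  reported but deliberately excluded from the decision because they are
  ambiguous outside a sleep context. User vocabularies in the same JSON
  schema are supported.
* **Whole-word multi-pattern matcher.** Notes are normalized into a
  lowercase alphanumeric token stream (every token keeps its exact raw
  character offsets); literal phrases are matched with a token trie scanned
  greedily — longest match at the leftmost position, non-overlapping — so
  "difficulty falling asleep" is one mention, not two. Regex entries
  (`less than \d+ hours`, `\w+ keeping \w+ up`, ...) run on the token
  stream with whole-token semantics. A brute-force reference matcher
  doubles as a correctness oracle in the tests.
* **Note classification rule.** A note is *positive* iff it contains at
  least one tier-1 match:

  label(note) = positive ⟺ ∃ match m in note with tier(m) = 1.

* **Evaluation.** Note-level confusion matrix and precision
  `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; span-level
  keyword coverage (fraction of gold annotation spans, tagged with one of
  nine sleep dimensions, that contain a tier-1 match); Cohen's kappa for
  annotator agreement.
* **Synthetic corpus generator.** Seeded, deterministic well-child-visit
  style notes with gold labels and standoff spans — including keyword-free
  paraphrased mentions (recall stressor) and negated sleep phrases
  (precision stressor) — so the whole pipeline is testable without patient
  data, which cannot be shared.

## Worked example

```r
library(pedsleepnlp)

vocab <- load_vocabulary("dse")
vocab_stats(vocab)
#> Vocabulary: 37 categories (30 tier-1, 7 tier-2); 354 literals + 6 regexes

m <- compile_matcher(vocab)
find_matches(m, "sleeps less than 6 hours on school nights")
#> # A tibble: 2 × 7
#>   start   end text              surface                kind    category       tier
#>   <int> <int> <chr>             <chr>                  <chr>   <chr>         <int>
#> 1     0     6 sleeps            "sleeps"               literal Sleep             1
#> 2     7    24 less than 6 hours "less than \\d+ hours" regex   Sleep duration    1

classify_note(m, "n1", "Lungs: mild wheezing bilaterally.")$label
#> [1] "negative"     # tier-2 matches never trigger identification

compute_metrics(confusion_from_counts(tp = 242, fp = 42, fn = 2, tn = 14))
#> precision 0.852  recall 0.992  F1 0.917
```

The match table gives 0-based half-open character offsets into the raw
note, the matched surface, and every (category, tier) the surface belongs
to. The metrics line is the note-level performance implied by a confusion
matrix: of 284 flagged notes 242 truly contained a mention (precision
0.852), and 242 of 244 mention-containing notes were flagged (recall
0.992).

A full synthetic round trip:

```r
corp <- generate_corpus(corpus_config(n_notes = 200, prevalence = 0.8,
                                      keyword_free_mention_rate = 0,
                                      negation_distractor_rate = 0, seed = 7))
preds <- classify_corpus(m, corp$notes)
compute_metrics(note_confusion(preds, corp$gold_labels))
#> precision 1.000  recall 1.000  F1 1.000
```

With the confounders switched off every planted mention embeds a verbatim
tier-1 surface, so the rule recovers the gold labels exactly; raising
`keyword_free_mention_rate` or `negation_distractor_rate` reproduces the
characteristic recall/precision failure modes of keyword systems.

There is also a small CLI (`vocab-stats`, `tag`, `classify`, `evaluate`,
`generate`); run the installed launcher with

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "pedsleep", package = "pedsleepnlp"))')" vocab-stats --vocab dse
```

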