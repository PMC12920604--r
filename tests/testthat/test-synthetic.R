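test_that("generation is deterministic under a seed and distinct across seeds", {
  cfg <- corpus_config(n_notes = 40, seed = 7)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$gold_labels, c2$gold_labels)
  expect_identical(c1$gold_spans, c2$gold_spans)
  c3 <- generate_corpus(corpus_config(n_notes = 40, seed = 8))
  expect_false(identical(c1$notes$text, c3$notes$text))
})

test_that("degenerate configurations behave as specified", {
  quiet <- generate_corpus(corpus_config(n_notes = 20, prevalence = 0,
                                         negation_distractor_rate = 0,
                                         tier2_only_rate = 0, seed = 3))
  expect_identical(nrow(quiet$gold_spans), 0L)
  expect_true(all(quiet$gold_labels$label == "negative"))
  expect_error(corpus_config(prevalence = 1.5), "\\[0, 1\\]")
  expect_error(corpus_config(n_notes = -1), "non-negative")
  expect_error(corpus_config(mentions_per_note = c(3, 1)), "min <= max")
})

test_that("a note is gold-positive exactly when it has a gold span", {
  corp <- generate_corpus(corpus_config(n_notes = 100, seed = 21))
  has_span <- corp$gold_labels$note_id %in% corp$gold_spans$note_id
  expect_identical(corp$gold_labels$label == "positive", has_span)
})

test_that("gold span offsets slice the note text to the mention sentence", {
  corp <- generate_corpus(corpus_config(n_notes = 60, seed = 9))
  expect_gt(nrow(corp$gold_spans), 0)
  texts <- stats::setNames(corp$notes$text, corp$notes$note_id)
  for (i in seq_len(nrow(corp$gold_spans))) {
    sp <- corp$gold_spans[i, ]
    expect_identical(substring(texts[[sp$note_id]], sp$start + 1, sp$end),
                     sp$text)
    expect_true(sp$dimension %in% sleep_dimensions())
  }
})

test_that("with confounders off the classifier recovers every positive note", {
  cfg <- corpus_config(n_notes = 200, prevalence = 0.8,
                       keyword_free_mention_rate = 0,
                       negation_distractor_rate = 0, seed = 13)
  corp <- generate_corpus(cfg)
  preds <- classify_corpus(dse_matcher, corp$notes)
  cm <- note_confusion(preds, corp$gold_labels)
  expect_identical(cm$fn, 0L)
  expect_identical(compute_metrics(cm)$recall, 1)
})

test_that("empirical prevalence stays inside the exact binomial 99% band", {
  corp <- generate_corpus(corpus_config(n_notes = 2000, prevalence = 0.5,
                                        seed = 17))
  n_pos <- sum(corp$gold_labels$label == "positive")
  expect_gte(n_pos, stats::qbinom(0.005, 2000, 0.5))
  expect_lte(n_pos, stats::qbinom(0.995, 2000, 0.5))
})

test_that("keyword-free paraphrases contain no vocabulary surface", {
  paraphrases <- unlist(pedsleepnlp:::.paraphrase_sentences, use.names = FALSE)
  fillers <- pedsleepnlp:::.filler_sentences
  for (s in c(paraphrases, fillers)) {
    expect_identical(nrow(find_matches(dse_matcher, s)), 0L)
  }
  for (s in pedsleepnlp:::.negation_sentences) {
    expect_true(any(find_matches(dse_matcher, s)$tier == 1L))
  }
  for (s in pedsleepnlp:::.tier2_sentences) {
    mt <- find_matches(dse_matcher, s)
    expect_true(all(mt$tier == 2L) && nrow(mt) > 0L)
  }
})

test_that("keyword-free mentions lower recall; more mentions per note recover it", {
  cfg1 <- corpus_config(n_notes = 400, prevalence = 0.8,
                        mentions_per_note = c(1L, 1L),
                        keyword_free_mention_rate = 0.5,
                        negation_distractor_rate = 0, seed = 23)
  corp1 <- generate_corpus(cfg1)
  rec1 <- compute_metrics(note_confusion(classify_corpus(dse_matcher, corp1$notes),
                                         corp1$gold_labels))$recall
  # each positive note has a single coin-flip chance to be missed
  expect_lt(rec1, 0.75)
  expect_gt(rec1, 0.3)
  cfg3 <- corpus_config(n_notes = 400, prevalence = 0.8,
                        mentions_per_note = c(3L, 3L),
                        keyword_free_mention_rate = 0.5,
                        negation_distractor_rate = 0, seed = 23)
  corp3 <- generate_corpus(cfg3)
  rec3 <- compute_metrics(note_confusion(classify_corpus(dse_matcher, corp3$notes),
                                         corp3$gold_labels))$recall
  expect_gt(rec3, rec1)
})

test_that("negation distractors reproduce the false-positive failure mode", {
  cfg <- corpus_config(n_notes = 150, prevalence = 0,
                       negation_distractor_rate = 1, tier2_only_rate = 0,
                       seed = 29)
  corp <- generate_corpus(cfg)
  cm <- note_confusion(classify_corpus(dse_matcher, corp$notes),
                       corp$gold_labels)
  expect_identical(cm$fp, 150L)
  met <- compute_metrics(cm)
  expect_true(is.na(met$precision) || met$precision < 0.1)
})

test_that("corpus files round-trip through the evaluation readers", {
  corp <- generate_corpus(corpus_config(n_notes = 50, seed = 31))
  dir <- file.path(tempdir(), "synthcorp")
  corpus_to_files(corp, dir)
  back <- read_corpus_dir(dir)
  expect_identical(back$notes, corp$notes)
  expect_identical(back$gold_labels, corp$gold_labels)
  expect_identical(as.data.frame(back$gold_spans),
                   as.data.frame(corp$gold_spans[, c("note_id", "dimension",
                                                     "start", "end")]))
  # written offsets slice the written notes to the original mention strings
  texts <- stats::setNames(back$notes$text, back$notes$note_id)
  for (i in seq_len(nrow(back$gold_spans))) {
    sp <- back$gold_spans[i, ]
    expect_identical(substring(texts[[sp$note_id]], sp$start + 1, sp$end),
                     corp$gold_spans$text[[i]])
  }
  # full pipeline on the files
  preds <- classify_corpus(dse_matcher, back$notes)
  cm <- note_confusion(preds, back$gold_labels)
  expect_identical(cm$tp + cm$fp + cm$fn + cm$tn, 50L)
  cov <- span_coverage(corpus_matches(dse_matcher, back$notes), back$gold_spans)
  expect_identical(cov$total_tags[cov$dimension == "ALL"], nrow(back$gold_spans))

  # empty corpus writes three valid empty files
  empty <- generate_corpus(corpus_config(n_notes = 0, seed = 1))
  dir2 <- file.path(tempdir(), "emptycorp")
  corpus_to_files(empty, dir2)
  back2 <- read_corpus_dir(dir2)
  expect_identical(nrow(back2$notes), 0L)
  expect_identical(nrow(back2$gold_labels), 0L)
  expect_identical(nrow(back2$gold_spans), 0L)
})
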