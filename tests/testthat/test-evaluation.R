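test_that("confusion matrix counts the four cells per note", {
  ids <- paste0("n", 1:5)
  gold <- stats::setNames(c("positive", "positive", "positive", "negative", "negative"), ids)
  cm <- note_confusion(gold, gold)
  expect_identical(unlist(cm[c("tp", "fp", "fn", "tn")]),
                   c(tp = 3L, fp = 0L, fn = 0L, tn = 2L))

  ids4 <- paste0("m", 1:4)
  cm2 <- note_confusion(stats::setNames(rep("positive", 4), ids4),
                        stats::setNames(rep("negative", 4), ids4))
  expect_identical(unlist(cm2[c("tp", "fp", "fn", "tn")]),
                   c(tp = 0L, fp = 4L, fn = 0L, tn = 0L))

  expect_error(note_confusion(stats::setNames("positive", "a"),
                              stats::setNames("positive", "b")),
               "same note ids")

  # random case cross-checked against an explicit per-note tally
  set.seed(405)
  ids20 <- paste0("r", 1:20)
  preds <- stats::setNames(sample(c("positive", "negative"), 20, TRUE), ids20)
  gold20 <- stats::setNames(sample(c("positive", "negative"), 20, TRUE), ids20)
  cm3 <- note_confusion(preds, gold20)
  tally <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (id in ids20) {
    cell <- if (preds[[id]] == "positive" && gold20[[id]] == "positive") "tp"
      else if (preds[[id]] == "positive") "fp"
      else if (gold20[[id]] == "positive") "fn"
      else "tn"
    tally[[cell]] <- tally[[cell]] + 1L
  }
  expect_identical(unlist(cm3[c("tp", "fp", "fn", "tn")]), tally)
  expect_identical(sum(tally), 20L)
})

test_that("published confusion tables yield the published metrics", {
  dse <- compute_metrics(confusion_from_counts(tp = 242, fp = 42, fn = 2, tn = 14))
  expect_identical(round_half_up(dse$precision, 3), 0.852)
  expect_identical(round_half_up(dse$recall, 3), 0.992)
  expect_identical(round_half_up(dse$f1, 3), 0.917)
  sea <- compute_metrics(confusion_from_counts(tp = 209, fp = 35, fn = 35, tn = 21))
  expect_identical(round_half_up(sea$precision, 3), 0.857)
  expect_identical(round_half_up(sea$recall, 3), 0.857)
  expect_identical(round_half_up(sea$f1, 3), 0.857)
})

test_that("undefined metrics are NA, never zero", {
  m <- compute_metrics(confusion_from_counts(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_true(is.na(m$precision) && is.na(m$recall) && is.na(m$f1))
  # fp only: precision defined (0), recall undefined
  m2 <- compute_metrics(confusion_from_counts(tp = 0, fp = 3, fn = 0, tn = 1))
  expect_identical(m2$precision, 0)
  expect_true(is.na(m2$recall))
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(406)
  for (rep in 1:50) {
    cm <- confusion_from_counts(tp = sample(0:50, 1), fp = sample(0:50, 1),
                                fn = sample(0:50, 1), tn = sample(0:50, 1))
    m <- compute_metrics(cm)
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    }
    if (cm$fp == 0 && cm$fn == 0 && cm$tp > 0) {
      expect_identical(c(m$precision, m$recall, m$f1), c(1, 1, 1))
    }
  }
})

test_that("recall delta matches the published 13.5-point gain", {
  dse <- compute_metrics(confusion_from_counts(242, 42, 2, 14))
  sea <- compute_metrics(confusion_from_counts(209, 35, 35, 21))
  expect_identical(recall_delta(dse, sea), 13.5)
  expect_identical(recall_delta(dse, dse), 0)
  expect_identical(recall_delta(sea, dse), -13.5)
  und <- compute_metrics(confusion_from_counts(0, 0, 0, 5))
  expect_error(recall_delta(dse, und), "undefined")
})

test_that("coverage percentages reproduce the published table arithmetic", {
  expect_identical(coverage_percent(892, 1156), 77.2)
  expect_identical(coverage_percent(110, 124), 88.7)
  expect_identical(coverage_percent(52, 96), 54.2)
  expect_true(is.na(coverage_percent(0, 0)))
})

test_that("span coverage counts tier-1 matches contained in annotations", {
  notes <- tibble::tibble(
    note_id = c("n1", "n2", "n3", "n4"),
    text = c("Parent reports bedtime struggles most evenings.",
             "He naps daily after school.",
             "Takes him an hour to settle in the evening.",
             "Started melatonin last week."))
  mbn <- corpus_matches(dse_matcher, notes)
  ann <- tibble::tibble(
    note_id = notes$note_id,
    dimension = c("sleep_behavior", "sleep_behavior",
                  "sleep_efficiency", "sleep_medication"),
    start = c(0L, 0L, 0L, 0L),
    end = nchar(notes$text))
  cov <- span_coverage(mbn, ann)
  all_row <- cov[cov$dimension == "ALL", ]
  expect_identical(all_row$total_tags, 4L)
  expect_identical(all_row$tags_with_keyword, 3L)
  expect_identical(all_row$percentage, 75.0)
  # a dimension with zero tags reports NA, not an error
  expect_true(is.na(cov$percentage[cov$dimension == "sleep_timing"]))
  # behavior dimension: "bedtime struggles" and "naps" each in one
  # annotation; tie broken lexicographically
  beh <- cov[cov$dimension == "sleep_behavior", ]
  expect_identical(beh$top_keyword, "bedtime struggles")
  expect_identical(beh$top_keyword_count, 1L)

  expect_error(span_coverage(mbn, tibble::tibble(
    note_id = "ghost", dimension = "sleep_behavior", start = 0L, end = 5L)),
    "not present")
})

test_that("containment is stricter than overlap mode", {
  notes <- tibble::tibble(note_id = "p1",
                          text = "difficulty falling asleep noted")
  mbn <- corpus_matches(dse_matcher, notes)
  ann <- tibble::tibble(note_id = "p1", dimension = "sleep_efficiency",
                        start = 0L, end = 10L) # cuts the match short
  strict <- span_coverage(mbn, ann)
  loose <- span_coverage(mbn, ann, mode = "overlap")
  expect_identical(strict$tags_with_keyword[strict$dimension == "ALL"], 0L)
  expect_identical(loose$tags_with_keyword[loose$dimension == "ALL"], 1L)
})

test_that("coverage never decreases when a tier-1 entry is added", {
  notes <- tibble::tibble(
    note_id = c("n1", "n2"),
    text = c("Takes him an hour to settle each evening.",
             "Started melatonin last week."))
  ann <- tibble::tibble(note_id = notes$note_id,
                        dimension = c("sleep_efficiency", "sleep_medication"),
                        start = c(0L, 0L), end = nchar(notes$text))
  base_cov <- span_coverage(corpus_matches(dse_matcher, notes), ann)
  grown <- vocabulary(c(dse_vocab$categories,
                        list(list(name = "Settling", tier = 1,
                                  literals = "settle", regexes = character(0)))),
                      version = "grown")
  grown_cov <- span_coverage(corpus_matches(compile_matcher(grown), notes), ann)
  base_all <- base_cov$percentage[base_cov$dimension == "ALL"]
  grown_all <- grown_cov$percentage[grown_cov$dimension == "ALL"]
  expect_true(grown_all >= base_all)
  expect_identical(grown_all, 100)
})

test_that("Cohen's kappa matches its definition", {
  expect_identical(cohen_kappa(c("a", "b", "c"), c("a", "b", "c")), 1.0)
  expect_identical(cohen_kappa(c("+", "+", "-", "-"), c("+", "-", "+", "-")), 0)
  expect_error(cohen_kappa(c("a", "b"), c("a")), "equal length")
  expect_error(cohen_kappa(character(0), character(0)), "non-empty")
  # single identical label throughout: chance agreement is 1, kappa is 1
  expect_identical(cohen_kappa(rep("x", 5), rep("x", 5)), 1.0)

  # random labelings cross-checked against an independent marginal tally
  set.seed(407)
  for (rep in 1:20) {
    labs <- c("beh", "dur", "med")
    a <- sample(labs, 50, TRUE)
    b <- sample(labs, 50, TRUE)
    p_o <- sum(a == b) / 50
    p_e <- 0
    for (l in labs) p_e <- p_e + (sum(a == l) / 50) * (sum(b == l) / 50)
    expect_equal(cohen_kappa(a, b), (p_o - p_e) / (1 - p_e))
  }
})
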