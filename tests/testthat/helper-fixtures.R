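# Shared fixtures: the packaged vocabulary is loaded and compiled once per
# test run; small helper constructors keep the tests terse.

dse_vocab <- load_vocabulary("dse")
dse_matcher <- compile_matcher(dse_vocab)

all_literal_surfaces <- function(v) {
  unique(unlist(lapply(v$categories, `[[`, "literals"), use.names = FALSE))
}

# A tiny custom vocabulary built in code.
tiny_vocab <- function() {
  vocabulary(list(
    list(name = "Snoring", tier = 1, literals = c("snore", "snores", "snoring"),
         regexes = character(0)),
    list(name = "Duration", tier = 1, literals = c("short sleep"),
         regexes = "less than \\d+ hours"),
    list(name = "Wheezing", tier = 2, literals = c("wheeze", "wheezing"),
         regexes = character(0))
  ), version = "tiny-1")
}

# Random note text assembled from vocabulary surfaces and filler words, with
# random case, punctuation and digits to stress normalization and regexes.
random_note_text <- function(surfaces, n_parts = 8) {
  fillers <- c("the", "patient", "today", "visit", "mom", "school", "he",
               "and", "with", "well", "exam", "notes", "plan", "history",
               "less", "than", "hours", "keeping", "him", "up", "doing",
               "things", "at", "night", "6", "10", "more")
  parts <- character(n_parts)
  for (k in seq_len(n_parts)) {
    parts[[k]] <- if (stats::runif(1) < 0.4) {
      surfaces[[sample.int(length(surfaces), 1L)]]
    } else {
      fillers[[sample.int(length(fillers), 1L)]]
    }
    if (stats::runif(1) < 0.15) parts[[k]] <- toupper(parts[[k]])
    if (stats::runif(1) < 0.1) parts[[k]] <- paste0(parts[[k]], ",")
  }
  paste(parts, collapse = " ")
}

expect_same_matches <- function(a, b) {
  expect_identical(as.data.frame(a), as.data.frame(b))
}

df_records_test <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}
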