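# Note-level identification rule: a note is positive when it contains at
# least one tier-1 mention. Tier-2 matches (ambiguous concepts such as
# "wheezing") are reported but never trigger a positive label.

# Split long-format match rows into tier-1 / tier-2 match groups. A match
# (one span + surface + kind, possibly several category rows) counts as
# tier-1 when any of its categories is tier 1.
partition_matches <- function(matches) {
  if (nrow(matches) == 0L) {
    return(list(tier1 = matches, tier2 = matches))
  }
  key <- paste(matches$start, matches$end, matches$surface, matches$kind, sep = "\r")
  t1_keys <- unique(key[matches$tier == 1L])
  list(tier1 = matches[key %in% t1_keys, , drop = FALSE],
       tier2 = matches[!(key %in% t1_keys), , drop = FALSE])
}

#' Classify a single note
#'
#' Runs [find_matches()] and applies the identification rule: the note is
#' `"positive"` iff at least one match carries a tier-1 category. A match
#' whose surface belongs to both a tier-1 and a tier-2 category (possible in
#' user vocabularies, not in the packaged bank) counts as tier-1.
#'
#' @param m A `sleep_matcher`.
#' @param note_id Identifier string for the note.
#' @param raw Note text.
#' @return An object of class `note_classification`: list with `note_id`,
#'   `label` (`"positive"`/`"negative"`), `tier1_matches`, `tier2_matches`
#'   (match tibbles as in [find_matches()]).
#' @examples
#' m <- compile_matcher(load_vocabulary("dse"))
#' classify_note(m, "n1", "Mom reports he snores loudly most nights.")$label
#' @export
classify_note <- function(m, note_id, raw) {
  stopifnot(inherits(m, "sleep_matcher"),
            is.character(note_id), length(note_id) == 1L)
  parts <- partition_matches(find_matches(m, raw))
  structure(list(
    note_id = note_id,
    label = if (nrow(parts$tier1) > 0L) "positive" else "negative",
    tier1_matches = parts$tier1,
    tier2_matches = parts$tier2
  ), class = "note_classification")
}

#' @export
print.note_classification <- function(x, ...) {
  cat("<note_classification> ", x$note_id, ": ", x$label, " (",
      nrow(x$tier1_matches), " tier-1 row(s), ",
      nrow(x$tier2_matches), " tier-2 row(s))\n", sep = "")
  invisible(x)
}

check_notes_frame <- function(notes) {
  if (!is.data.frame(notes) || !all(c("note_id", "text") %in% names(notes))) {
    stop("`notes` must be a data frame with columns `note_id` and `text`",
         call. = FALSE)
  }
  if (anyDuplicated(notes$note_id)) {
    stop("duplicate note_id(s): ",
         paste(unique(notes$note_id[duplicated(notes$note_id)]), collapse = ", "),
         call. = FALSE)
  }
  notes
}

#' Classify a corpus of notes
#'
#' @param m A `sleep_matcher`.
#' @param notes Data frame with columns `note_id` (unique) and `text`.
#' @return A tibble with one row per note, in input order: `note_id`,
#'   `label`, `n_tier1`, `n_tier2` (counts of distinct tier-1 / tier-2
#'   match spans). The attribute `"summary"` holds `c(positive = ,
#'   negative = )` counts.
#' @export
classify_corpus <- function(m, notes) {
  notes <- check_notes_frame(notes)
  res <- lapply(seq_len(nrow(notes)), function(i) {
    cl <- classify_note(m, as.character(notes$note_id[[i]]), notes$text[[i]])
    tibble::tibble(
      note_id = cl$note_id, label = cl$label,
      n_tier1 = n_distinct_spans(cl$tier1_matches),
      n_tier2 = n_distinct_spans(cl$tier2_matches))
  })
  out <- if (length(res) == 0L) {
    tibble::tibble(note_id = character(0), label = character(0),
                   n_tier1 = integer(0), n_tier2 = integer(0))
  } else {
    do.call(rbind, res)
  }
  attr(out, "summary") <- c(positive = sum(out$label == "positive"),
                            negative = sum(out$label == "negative"))
  out
}

n_distinct_spans <- function(matches) {
  if (nrow(matches) == 0L) return(0L)
  length(unique(paste(matches$start, matches$end, matches$surface,
                      matches$kind, sep = "\r")))
}

#' Run the matcher over a corpus, keeping every match
#'
#' Convenience for span-coverage analysis: returns the raw match tables per
#' note rather than only the note-level labels.
#'
#' @inheritParams classify_corpus
#' @return Named list (by `note_id`) of match tibbles from [find_matches()].
#' @export
corpus_matches <- function(m, notes) {
  notes <- check_notes_frame(notes)
  out <- lapply(seq_len(nrow(notes)), function(i) find_matches(m, notes$text[[i]]))
  names(out) <- as.character(notes$note_id)
  out
}
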