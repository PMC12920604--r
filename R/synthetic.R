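# Seeded generator of synthetic well-child-visit-style notes with gold
# note labels and gold standoff annotation spans.
#
# Real pediatric clinical notes cannot be shared, so every downstream module
# is exercised on synthetic notes built from short clinic-note sentence
# frames (HPI/ROS/plan style). Positive notes carry 1-3 sleep mentions, each
# rendered either from a keyword-bearing template that embeds a verbatim
# tier-1 surface, or from a hand-written keyword-free paraphrase (the
# mechanism behind incomplete span coverage: a human annotator tags the
# sentence, the keyword matcher has nothing to find in it). Negative notes
# carry filler prose plus, at configurable rates, negated sleep phrases
# ("Denies snoring...") that drive false positives, and tier-2-only text
# ("Mild wheezing...") that must NOT flip the prediction.
#
# Every paraphrase and filler template is verified at generation time to
# contain no vocabulary match at all; negation templates must contain a
# tier-1 surface and tier-2 templates a tier-2 (and no tier-1) surface.

.filler_sentences <- c(
  "Well child visit for annual physical today.",
  "Growth tracking along expected percentiles.",
  "Immunizations reviewed and brought current.",
  "Diet includes fruits and vegetables daily.",
  "Physical exam unremarkable throughout.",
  "Vision and hearing screening passed.",
  "Denies fever, cough, or congestion.",
  "Counseled on helmet and seat belt safety.",
  "Heart regular rate and rhythm without murmur.",
  "Lungs clear to auscultation bilaterally.",
  "Abdomen soft and nontender on exam.",
  "Follow up in one year or as needed.")

.negation_sentences <- c(
  "Denies snoring or apnea at this time.",
  "No sleep concerns reported today.",
  "Patient does not snore often.",
  "Mom states no trouble sleeping currently.")

.tier2_sentences <- c(
  "Mild wheezing noted on lung exam.",
  "Seems irritable in the late afternoons.",
  "Reports occasional dizziness with standing.",
  "Teacher describes him as inattentive at times.")

# Keyword-bearing mention frames per dimension: prefix + verbatim tier-1
# surface + suffix. Surfaces are drawn from the packaged bank.
.mention_frames <- list(
  sleep_behavior = list(
    frames = list(c("Parent reports ", " most evenings."),
                  c("Ongoing ", " described at home.")),
    surfaces = c("bedtime struggles", "sleepwalking", "sleep talking",
                 "teeth grinding")),
  sleep_satisfaction = list(
    frames = list(c("Mom describes ", " over the past month."),
                  c("Patient endorses ", " recently.")),
    surfaces = c("poor sleep", "restless sleep", "fair sleep quality",
                 "disturbed sleep")),
  alertness_daytime_sleepiness = list(
    frames = list(c("Teacher reports he seems ", " at school."),
                  c("Noted to be ", " during the day.")),
    surfaces = c("sleepy", "drowsy", "tired", "fatigued")),
  sleep_timing = list(
    frames = list(c("Family notes ", " on school nights."),
                  c("Reviewed ", " with the family.")),
    surfaces = c("inconsistent bedtime", "delayed sleep phase",
                 "bedtime schedule", "sleeps late")),
  sleep_efficiency = list(
    frames = list(c("Parent reports ", " several times weekly."),
                  c("He has ", " on many nights.")),
    surfaces = c("difficulty falling asleep", "trouble staying asleep",
                 "nighttime awakenings", "interrupted sleep", "broken sleep")),
  sleep_duration = list(
    frames = list(c("Concern for ", " during the school week."),
                  c("History significant for ", " this year.")),
    surfaces = c("insufficient sleep", "short sleep", "sleep deprivation",
                 "not getting enough sleep")),
  sleep_medication = list(
    frames = list(c("Currently taking ", " at night."),
                  c("Family restarted ", " last week.")),
    surfaces = c("melatonin", "sleep aid", "sleeping pills", "clonidine")),
  sleep_disorder = list(
    frames = list(c("History of ", " per prior records."),
                  c("Assessment includes ", " today.")),
    surfaces = c("insomnia", "obstructive sleep apnea", "narcolepsy",
                 "restless leg", "snoring")),
  sleep_intervention = list(
    frames = list(c("Discussed ", " strategies with the family."),
                  c("Plan to reinforce ", " at home.")),
    surfaces = c("sleep hygiene", "bedtime routine", "sleep habits",
                 "nighttime routine")))

# Keyword-free paraphrases per dimension: a clinician-voice sentence a human
# annotator would tag as a sleep mention, containing no bank surface at all.
.paraphrase_sentences <- list(
  sleep_behavior = c(
    "Child clings to parent and protests at lights out.",
    "Needs the television on before settling down each evening."),
  sleep_satisfaction = c(
    "Mom feels his rest is rarely refreshing.",
    "He says he never feels rested in the morning."),
  alertness_daytime_sleepiness = c(
    "Teacher notes he nods off during afternoon lessons.",
    "Struggles to keep his eyes open in class."),
  sleep_timing = c(
    "Lights out around nine, up for school at six.",
    "Turns in very late and rises well after sunrise on weekends."),
  sleep_efficiency = c(
    "Takes him over an hour to settle after lights out.",
    "Long stretches lying awake in the dark before drifting off."),
  sleep_duration = c(
    "Gets roughly six hours on school nights.",
    "His nightly total falls short of what is recommended for his age."),
  sleep_medication = c(
    "Takes a nightly supplement to help him settle.",
    "Uses an over the counter remedy each evening."),
  sleep_disorder = c(
    "Longstanding nighttime breathing trouble noted by ENT.",
    "Concern for pauses in breathing overnight raised by dad."),
  sleep_intervention = c(
    "Family started a consistent wind down plan each evening.",
    "Counselor suggested dimming lights and quiet reading before bed."))

#' Configuration for the synthetic note generator
#'
#' Defaults mirror the published study conditions: 300 notes of which 244
#' contained a mention (prevalence 244/300), 1-3 mentions per positive note,
#' per-dimension mention weights proportional to the published per-dimension
#' annotation totals, a keyword-free paraphrase rate of 0.228 (one minus the
#' 77.2% overall span coverage), and a negation-distractor rate of 0.75
#' (42 of the 56 mention-free notes were falsely flagged).
#'
#' @param n_notes Number of notes to generate.
#' @param prevalence Probability a note is gold-positive.
#' @param mentions_per_note Integer range `c(min, max)` of mentions per
#'   positive note.
#' @param dimension_weights Named non-negative weights over the nine
#'   dimensions of [sleep_dimensions()] (need not sum to 1).
#' @param keyword_free_mention_rate Probability a gold mention is rendered
#'   from a paraphrase containing no vocabulary surface.
#' @param negation_distractor_rate Probability a gold-negative note contains
#'   a negated sleep phrase (false-positive driver).
#' @param tier2_only_rate Probability a gold-negative note contains
#'   tier-2-only text (must not flip the prediction).
#' @param seed Integer seed; the generator is deterministic given the full
#'   configuration.
#' @return Object of class `corpus_config` (a validated list).
#' @export
corpus_config <- function(n_notes = 300,
                          prevalence = 244 / 300,
                          mentions_per_note = c(1L, 3L),
                          dimension_weights = c(
                            sleep_behavior = 96, sleep_satisfaction = 124,
                            alertness_daytime_sleepiness = 143,
                            sleep_timing = 87, sleep_efficiency = 164,
                            sleep_duration = 40, sleep_medication = 199,
                            sleep_disorder = 204, sleep_intervention = 99),
                          keyword_free_mention_rate = 0.228,
                          negation_distractor_rate = 0.75,
                          tier2_only_rate = 0.25,
                          seed = 1L) {
  probs <- c(prevalence = prevalence,
             keyword_free_mention_rate = keyword_free_mention_rate,
             negation_distractor_rate = negation_distractor_rate,
             tier2_only_rate = tier2_only_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[!is.finite(probs) | probs < 0 | probs > 1],
               collapse = ", "), call. = FALSE)
  }
  if (length(n_notes) != 1L || is.na(n_notes) || n_notes < 0 ||
      n_notes != round(n_notes)) {
    stop("`n_notes` must be a non-negative integer", call. = FALSE)
  }
  if (length(mentions_per_note) != 2L || any(mentions_per_note < 1L) ||
      mentions_per_note[[1L]] > mentions_per_note[[2L]]) {
    stop("`mentions_per_note` must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  dims <- sleep_dimensions()
  if (!all(dims %in% names(dimension_weights))) {
    stop("`dimension_weights` must name all nine dimensions", call. = FALSE)
  }
  w <- as.numeric(dimension_weights[dims])
  if (any(w < 0) || sum(w) <= 0) {
    stop("`dimension_weights` must be non-negative and not all zero",
         call. = FALSE)
  }
  structure(list(
    n_notes = as.integer(n_notes), prevalence = prevalence,
    mentions_per_note = as.integer(mentions_per_note),
    dimension_weights = stats::setNames(w, dims),
    keyword_free_mention_rate = keyword_free_mention_rate,
    negation_distractor_rate = negation_distractor_rate,
    tier2_only_rate = tier2_only_rate,
    seed = as.integer(seed)
  ), class = "corpus_config")
}

pick <- function(x) x[[sample.int(length(x), 1L)]]

has_tier <- function(matches, tier) nrow(matches) > 0L && any(matches$tier == tier)

verify_templates <- function(m) {
  for (s in c(.filler_sentences, unlist(.paraphrase_sentences, use.names = FALSE))) {
    if (nrow(find_matches(m, s)) > 0L) {
      stop("template verification failed: \"", s,
           "\" matches the vocabulary but must be keyword-free", call. = FALSE)
    }
  }
  for (s in .negation_sentences) {
    if (!has_tier(find_matches(m, s), 1L)) {
      stop("template verification failed: negation distractor \"", s,
           "\" contains no tier-1 surface", call. = FALSE)
    }
  }
  for (s in .tier2_sentences) {
    mt <- find_matches(m, s)
    if (has_tier(mt, 1L) || !has_tier(mt, 2L)) {
      stop("template verification failed: \"", s,
           "\" must contain tier-2 and no tier-1 surfaces", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic annotated note corpus
#'
#' Deterministic given the configuration (a single RNG stream is consumed in
#' a fixed order: per note the positive/negative draw, then sentence and
#' mention draws left to right). Gold annotation spans cover the full
#' mention sentence, in 0-based half-open raw offsets; a note is
#' gold-positive if and only if it has at least one gold span.
#'
#' @param config A [corpus_config()] object.
#' @param vocab Vocabulary used to verify the templates (default: the
#'   packaged DSE bank). Generation itself only uses the built-in templates;
#'   with a vocabulary that diverges from the packaged bank, template
#'   verification may fail.
#' @return Object of class `synthetic_corpus`: list with `notes` (tibble
#'   `note_id`, `text`), `gold_labels` (tibble `note_id`, `label`),
#'   `gold_spans` (tibble `note_id`, `dimension`, `start`, `end`, `text`)
#'   and `config` (the configuration echo).
#' @examples
#' corp <- generate_corpus(corpus_config(n_notes = 10, seed = 42))
#' corp$gold_labels
#' @export
generate_corpus <- function(config, vocab = NULL) {
  stopifnot(inherits(config, "corpus_config"))
  if (is.null(vocab)) vocab <- load_vocabulary("dse")
  matcher <- compile_matcher(vocab)
  verify_templates(matcher)

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(config$seed)

  dims <- sleep_dimensions()
  w <- config$dimension_weights / sum(config$dimension_weights)
  notes <- vector("list", config$n_notes)
  labels <- character(config$n_notes)
  spans <- list()

  for (i in seq_len(config$n_notes)) {
    note_id <- sprintf("note-%05d", i)
    positive <- stats::runif(1) < config$prevalence
    lead <- pick(.filler_sentences)
    trail <- pick(.filler_sentences)
    mid <- character(0)
    mention_flags <- logical(0) # which mid sentences are gold mentions
    mention_dims <- character(0)
    if (positive) {
      k <- config$mentions_per_note[[1L]] +
        sample.int(config$mentions_per_note[[2L]] -
                     config$mentions_per_note[[1L]] + 1L, 1L) - 1L
      for (j in seq_len(k)) {
        d <- dims[[sample.int(length(dims), 1L, prob = w)]]
        if (stats::runif(1) < config$keyword_free_mention_rate) {
          sent <- pick(.paraphrase_sentences[[d]])
        } else {
          fr <- pick(.mention_frames[[d]]$frames)
          surf <- pick(.mention_frames[[d]]$surfaces)
          sent <- paste0(fr[[1L]], surf, fr[[2L]])
        }
        mid <- c(mid, sent)
        mention_flags <- c(mention_flags, TRUE)
        mention_dims <- c(mention_dims, d)
      }
    } else {
      if (stats::runif(1) < config$negation_distractor_rate) {
        mid <- c(mid, pick(.negation_sentences))
        mention_flags <- c(mention_flags, FALSE)
        mention_dims <- c(mention_dims, NA_character_)
      }
      if (stats::runif(1) < config$tier2_only_rate) {
        mid <- c(mid, pick(.tier2_sentences))
        mention_flags <- c(mention_flags, FALSE)
        mention_dims <- c(mention_dims, NA_character_)
      }
    }
    sentences <- c(lead, mid, trail)
    text <- paste(sentences, collapse = " ")
    # offsets of each sentence in the assembled note (0-based half-open)
    pos <- 0L
    for (s_idx in seq_along(sentences)) {
      s_len <- nchar(sentences[[s_idx]])
      if (s_idx > 1L && s_idx - 1L <= length(mid) && mention_flags[[s_idx - 1L]]) {
        spans[[length(spans) + 1L]] <- tibble::tibble(
          note_id = note_id, dimension = mention_dims[[s_idx - 1L]],
          start = pos, end = pos + s_len,
          text = sentences[[s_idx]])
      }
      pos <- pos + s_len + 1L # the joining space
    }
    notes[[i]] <- tibble::tibble(note_id = note_id, text = text)
    labels[[i]] <- if (positive) "positive" else "negative"
  }

  notes_tbl <- if (config$n_notes == 0L) {
    tibble::tibble(note_id = character(0), text = character(0))
  } else do.call(rbind, notes)
  spans_tbl <- if (length(spans) == 0L) {
    tibble::tibble(note_id = character(0), dimension = character(0),
                   start = integer(0), end = integer(0), text = character(0))
  } else do.call(rbind, spans)
  structure(list(
    notes = notes_tbl,
    gold_labels = tibble::tibble(note_id = notes_tbl$note_id, label = labels),
    gold_spans = spans_tbl,
    config = config
  ), class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$notes), " notes (",
      sum(x$gold_labels$label == "positive"), " gold-positive), ",
      nrow(x$gold_spans), " gold spans; seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus to a directory of JSONL files
#'
#' Writes `notes.jsonl` (`{note_id, text}`), `labels.jsonl`
#' (`{note_id, label}`) and `annotations.jsonl`
#' (`{note_id, dimension, start, end}`) in the formats the evaluation
#' readers consume; [read_corpus_dir()] round-trips them losslessly.
#'
#' @param corpus A `synthetic_corpus` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
corpus_to_files <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_jsonl(df_records(corpus$notes), file.path(dir, "notes.jsonl"))
  write_jsonl(df_records(corpus$gold_labels), file.path(dir, "labels.jsonl"))
  ann <- corpus$gold_spans[, c("note_id", "dimension", "start", "end"), drop = FALSE]
  write_jsonl(df_records(ann), file.path(dir, "annotations.jsonl"))
  invisible(dir)
}

df_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Read a corpus directory written by [corpus_to_files()]
#'
#' @param dir Directory containing `notes.jsonl`, `labels.jsonl`,
#'   `annotations.jsonl`.
#' @return List with tibbles `notes`, `gold_labels`, `gold_spans`.
#' @export
read_corpus_dir <- function(dir) {
  list(notes = read_notes_jsonl(file.path(dir, "notes.jsonl")),
       gold_labels = read_labels_jsonl(file.path(dir, "labels.jsonl")),
       gold_spans = read_annotations_jsonl(file.path(dir, "annotations.jsonl")))
}
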