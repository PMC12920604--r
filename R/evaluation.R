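# Evaluation arithmetic: note-level confusion matrix with precision /
# recall / F1, span-level keyword coverage by annotation dimension, and
# Cohen's kappa for annotator agreement.
#
# Display rounding follows the conventions of the published tables: metrics
# to 3 decimals, percentages to 1 decimal, half rounded away from zero.
# Undefined metrics (zero denominators) are NA, never silently 0.

#' Round half away from zero
#'
#' Display-rounding helper: `round_half_up(0.8525, 3)` is `0.853`, where
#' base `round()` would give banker's rounding. Used for all reported
#' metrics and percentages.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector (`NA` stays `NA`).
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny epsilon guards against binary representations just under .5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

as_label_vector <- function(x, arg) {
  if (is.data.frame(x)) {
    if (!all(c("note_id", "label") %in% names(x))) {
      stop("`", arg, "` data frame needs columns `note_id` and `label`",
           call. = FALSE)
    }
    out <- as.character(x$label)
    names(out) <- as.character(x$note_id)
    x <- out
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("`", arg, "` must be a named vector (names = note ids) or a ",
         "data frame with note_id/label columns", call. = FALSE)
  }
  bad <- setdiff(unique(as.character(x)), c("positive", "negative"))
  if (length(bad)) stop("`", arg, "` has invalid label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' Note-level confusion matrix
#'
#' Positive means "the note contains at least one sleep-related mention".
#' Rows are counted per note: true positives are notes positive in both
#' `predictions` and `gold`, false positives are predicted-positive
#' gold-negative notes, and so on.
#'
#' @param predictions,gold Named character vectors of `"positive"` /
#'   `"negative"` (names = note ids), or data frames with `note_id` and
#'   `label` columns. Key sets must be identical.
#' @return Object of class `note_confusion`: list with integer `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
note_confusion <- function(predictions, gold) {
  predictions <- as_label_vector(predictions, "predictions")
  gold <- as_label_vector(gold, "gold")
  if (!setequal(names(predictions), names(gold)) ||
      length(predictions) != length(gold)) {
    stop("predictions and gold must cover the same note ids", call. = FALSE)
  }
  g <- gold[names(predictions)]
  p_pos <- predictions == "positive"
  g_pos <- g == "positive"
  structure(list(tp = sum(p_pos & g_pos), fp = sum(p_pos & !g_pos),
                 fn = sum(!p_pos & g_pos), tn = sum(!p_pos & !g_pos)),
            class = "note_confusion")
}

#' Build a confusion matrix from its four cell counts
#'
#' Used to re-derive metrics from published confusion tables.
#'
#' @param tp,fp,fn,tn Non-negative integer counts of notes.
#' @return Object of class `note_confusion`.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "note_confusion")
}

#' @export
print.note_confusion <- function(x, ...) {
  cat("          gold+  gold-\n")
  cat(sprintf("pred+  %6d %6d\n", x$tp, x$fp))
  cat(sprintf("pred-  %6d %6d\n", x$fn, x$tn))
  invisible(x)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' * precision = tp / (tp + fp): the proportion of keyword-flagged notes
#'   that truly contain a mention;
#' * recall = tp / (tp + fn): the proportion of truly mention-containing
#'   notes that the keywords flag;
#' * F1 = harmonic mean of the two.
#'
#' Each is `NA` when its denominator is zero (F1 additionally requires both
#' to be defined with a positive sum). Values are stored at full precision;
#' the print method displays 3 decimals.
#'
#' @param cm A `note_confusion` object.
#' @return Object of class `note_metrics`: list with numeric `precision`,
#'   `recall`, `f1` (possibly `NA`).
#' @examples
#' compute_metrics(confusion_from_counts(tp = 242, fp = 42, fn = 2, tn = 14))
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "note_confusion"))
  precision <- if (cm$tp + cm$fp > 0L) cm$tp / (cm$tp + cm$fp) else NA_real_
  recall <- if (cm$tp + cm$fn > 0L) cm$tp / (cm$tp + cm$fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "note_metrics")
}

#' @export
print.note_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", round_half_up(v, 3))
  cat("precision ", fmt(x$precision), "  recall ", fmt(x$recall),
      "  F1 ", fmt(x$f1), "\n", sep = "")
  invisible(x)
}

#' Recall difference in percentage points
#'
#' @param m_a,m_b `note_metrics` objects with defined recall.
#' @return `(recall_a - recall_b) * 100`, rounded to 1 decimal.
#' @export
recall_delta <- function(m_a, m_b) {
  stopifnot(inherits(m_a, "note_metrics"), inherits(m_b, "note_metrics"))
  if (is.na(m_a$recall) || is.na(m_b$recall)) {
    stop("recall is undefined for at least one metrics object", call. = FALSE)
  }
  round_half_up((m_a$recall - m_b$recall) * 100, 1)
}

#' Coverage percentage from counts
#'
#' @param hits Number of annotation spans containing a keyword.
#' @param total Total annotation spans.
#' @return `100 * hits / total` rounded to 1 decimal, or `NA` when
#'   `total == 0`.
#' @export
coverage_percent <- function(hits, total) {
  if (length(total) != 1L || length(hits) != 1L) stop("scalar counts expected")
  if (total == 0) return(NA_real_)
  round_half_up(100 * hits / total, 1)
}

#' Span-level keyword coverage by annotation dimension
#'
#' For each of the nine sleep dimensions, counts how many gold annotation
#' spans contain at least one tier-1 keyword match. "Contains" defaults to
#' full containment of the match interval within the annotation interval
#' (the strictest reading: stray partial overlaps earn no credit);
#' `mode = "overlap"` credits any intersection instead. Also reports, per
#' dimension, the entry surface present inside the largest number of that
#' dimension's annotations (each surface counted at most once per
#' annotation; ties broken lexicographically), and an `ALL` summary row.
#'
#' @param matches_by_note Named list of match tibbles (see
#'   [corpus_matches()]); must contain every annotated note id (possibly
#'   with an empty table).
#' @param annotations Tibble/data frame with columns `note_id`, `dimension`,
#'   `start`, `end` (0-based half-open).
#' @param mode `"containment"` (default) or `"overlap"`.
#' @return Object of class `coverage_table`: tibble with columns
#'   `dimension` (the nine dimensions plus `"ALL"`), `total_tags`,
#'   `tags_with_keyword`, `percentage` (1 decimal, `NA` when no tags), and
#'   `top_keyword` / `top_keyword_count`.
#' @export
span_coverage <- function(matches_by_note, annotations,
                          mode = c("containment", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(is.list(matches_by_note))
  if (!is.data.frame(annotations) ||
      !all(c("note_id", "dimension", "start", "end") %in% names(annotations))) {
    stop("`annotations` needs columns note_id, dimension, start, end",
         call. = FALSE)
  }
  unknown <- setdiff(unique(as.character(annotations$note_id)), names(matches_by_note))
  if (length(unknown)) {
    stop("annotation note id(s) not present in matches_by_note: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  bad_dim <- setdiff(unique(as.character(annotations$dimension)), sleep_dimensions())
  if (length(bad_dim)) {
    stop("unknown annotation dimension(s): ", paste(bad_dim, collapse = ", "),
         call. = FALSE)
  }
  n_ann <- nrow(annotations)
  contained <- logical(n_ann)
  surfaces_inside <- vector("list", n_ann)
  for (i in seq_len(n_ann)) {
    mt <- matches_by_note[[as.character(annotations$note_id[[i]])]]
    if (is.null(mt) || nrow(mt) == 0L) next
    t1 <- mt[mt$tier == 1L, , drop = FALSE]
    if (nrow(t1) == 0L) next
    a_start <- annotations$start[[i]]
    a_end <- annotations$end[[i]]
    inside <- if (mode == "containment") {
      t1$start >= a_start & t1$end <= a_end
    } else {
      t1$start < a_end & t1$end > a_start
    }
    if (any(inside)) {
      contained[[i]] <- TRUE
      surfaces_inside[[i]] <- unique(t1$surface[inside])
    }
  }
  dim_row <- function(dims, label) {
    sel <- as.character(annotations$dimension) %in% dims
    total <- sum(sel)
    hits <- sum(contained[sel])
    surf <- unlist(surfaces_inside[sel], use.names = FALSE)
    if (length(surf)) {
      counts <- table(surf)
      ord <- order(-as.integer(counts), names(counts)) # ties: lexicographic
      top <- names(counts)[ord[[1L]]]
      top_n <- as.integer(counts[ord[[1L]]])
    } else {
      top <- NA_character_
      top_n <- NA_integer_
    }
    tibble::tibble(dimension = label, total_tags = total,
                   tags_with_keyword = hits,
                   percentage = coverage_percent(hits, total),
                   top_keyword = top, top_keyword_count = top_n)
  }
  rows <- c(list(dim_row(sleep_dimensions(), "ALL")),
            lapply(sleep_dimensions(), function(d) dim_row(d, d)))
  out <- do.call(rbind, rows)
  class(out) <- c("coverage_table", class(out))
  out
}

#' Cohen's kappa for two labelings
#'
#' Chance-corrected agreement: `(p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` computed from the two labelings' marginal frequencies.
#' When `p_e` is 1 (both raters use a single identical label throughout),
#' agreement is perfect by construction and 1.0 is returned.
#'
#' @param labels_a,labels_b Equal-length vectors (length >= 1) of category
#'   labels; any atomic label type.
#' @return Kappa as a single numeric value.
#' @examples
#' cohen_kappa(c("p", "p", "n", "n"), c("p", "n", "p", "n")) # 0: chance level
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  if (length(a) != length(b)) stop("labelings must have equal length", call. = FALSE)
  if (length(a) < 1L) stop("labelings must be non-empty", call. = FALSE)
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  n <- length(a)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) return(1.0)
  (p_o - p_e) / (1 - p_e)
}
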