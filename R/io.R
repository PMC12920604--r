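# JSON-lines readers/writers for note-shaped data. One JSON object per line;
# all character offsets on disk are 0-based half-open, matching the in-memory
# match/annotation contracts.

#' Read a JSON-lines file
#'
#' @param path File path.
#' @return List with one parsed record per non-empty line. Malformed lines
#'   raise an error naming the line number.
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  lapply(seq_along(idx), function(k) {
    tryCatch(jsonlite::fromJSON(lines[[idx[[k]]]], simplifyVector = FALSE),
             error = function(e) stop("malformed JSON on line ", idx[[k]], " of ",
                                      path, ": ", conditionMessage(e), call. = FALSE))
  })
}

#' Write records as JSON lines
#'
#' @param records A list of records (each converted to one JSON object) or a
#'   data frame (one object per row).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  if (is.data.frame(records)) {
    records <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, , drop = FALSE]))
  }
  lines <- vapply(records, function(rec) {
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"))
  }, character(1))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  if (length(lines)) writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  invisible(path)
}

#' Read notes from JSONL (`{note_id, text}` per line)
#' @param path File path.
#' @return Tibble with columns `note_id`, `text`.
#' @export
read_notes_jsonl <- function(path) {
  recs <- read_jsonl(path)
  check_fields(recs, c("note_id", "text"), path)
  tibble::tibble(
    note_id = vapply(recs, function(r) as.character(r$note_id), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)))
}

#' Read gold note labels from JSONL (`{note_id, label}` per line)
#' @param path File path.
#' @return Tibble with columns `note_id`, `label` (`"positive"`/`"negative"`).
#' @export
read_labels_jsonl <- function(path) {
  recs <- read_jsonl(path)
  check_fields(recs, c("note_id", "label"), path)
  out <- tibble::tibble(
    note_id = vapply(recs, function(r) as.character(r$note_id), character(1)),
    label = vapply(recs, function(r) as.character(r$label), character(1)))
  bad <- setdiff(unique(out$label), c("positive", "negative"))
  if (length(bad)) stop("invalid label(s) in ", path, ": ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out
}

#' Read standoff annotations from JSONL (`{note_id, dimension, start, end}`)
#' @param path File path.
#' @return Tibble with columns `note_id`, `dimension`, `start`, `end`
#'   (0-based half-open character offsets).
#' @export
read_annotations_jsonl <- function(path) {
  recs <- read_jsonl(path)
  check_fields(recs, c("note_id", "dimension", "start", "end"), path)
  out <- tibble::tibble(
    note_id = vapply(recs, function(r) as.character(r$note_id), character(1)),
    dimension = vapply(recs, function(r) as.character(r$dimension), character(1)),
    start = vapply(recs, function(r) as.integer(r$start), integer(1)),
    end = vapply(recs, function(r) as.integer(r$end), integer(1)))
  bad <- setdiff(unique(out$dimension), sleep_dimensions())
  if (length(bad)) stop("unknown dimension(s) in ", path, ": ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(out$start >= out$end)) stop("annotation with start >= end in ", path,
                                      call. = FALSE)
  out
}

check_fields <- function(recs, fields, path) {
  for (i in seq_along(recs)) {
    missing <- setdiff(fields, names(recs[[i]]))
    if (length(missing)) {
      stop("record ", i, " of ", path, " is missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(recs)
}

#' Write per-note match records as JSONL
#'
#' One object per note: `{note_id, matches: [{start, end, text, surface,
#' kind, categories: [{name, tier}]}]}`, with the long-format match rows of
#' [find_matches()] re-nested so each match span lists all its categories.
#'
#' @param matches_by_note Named list of match tibbles (see [corpus_matches()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matches_jsonl <- function(matches_by_note, path) {
  recs <- lapply(names(matches_by_note), function(id) {
    df <- matches_by_note[[id]]
    groups <- if (nrow(df) == 0L) list() else {
      key <- paste(df$start, df$end, df$surface, df$kind, sep = "\r")
      lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))), function(ix) {
        first <- ix[[1L]]
        list(start = df$start[[first]], end = df$end[[first]],
             text = df$text[[first]], surface = df$surface[[first]],
             kind = df$kind[[first]],
             categories = lapply(ix, function(i) list(name = df$category[[i]],
                                                      tier = df$tier[[i]])))
      })
    }
    list(note_id = id, matches = unname(groups))
  })
  write_jsonl(recs, path)
}
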