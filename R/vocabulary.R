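# The two-tier keyword bank: load / validate / summarize / save.
#
# The packaged asset `dse_vocabulary.json` is a verbatim transcription of the
# published Davenport-Sirrianni Expanded (DSE) pediatric sleep keyword bank:
# 37 high-level categories, of which 30 are tier 1 (used by the note
# identification rule) and 7 are tier 2 (reported but not used for
# identification, because terms like "wheezing" are ambiguous outside a sleep
# context). Apparent misspellings in the published bank (e.g. "bendryl",
# "trazadone") and repeated phrases are preserved on purpose: they may be
# deliberate note-dialect coverage, and fidelity to the published bank is the
# contract. The validator flags them; nothing "fixes" them.

#' Construct a vocabulary object
#'
#' Low-level constructor used by [load_vocabulary()] and by tests that need
#' to build small vocabularies in code. Performs structural checks only
#' (names, tiers, non-empty categories); use [validate_vocabulary()] for a
#' full content report.
#'
#' @param categories A list of categories, each a list with elements `name`
#'   (string), `tier` (1 or 2), `literals` (character vector) and `regexes`
#'   (character vector). Either of `literals`/`regexes` may be empty but not
#'   both.
#' @param version Version string recorded in the object (the packaged DSE
#'   asset is `"table2-v1"`).
#' @return An object of class `sleep_vocabulary`.
#' @export
vocabulary <- function(categories, version = "user") {
  if (!is.list(categories) || length(categories) == 0L) {
    stop("`categories` must be a non-empty list", call. = FALSE)
  }
  categories <- lapply(seq_along(categories), function(i) {
    cat_i <- categories[[i]]
    nm <- cat_i$name
    if (is.null(nm) || !is.character(nm) || length(nm) != 1L || !nzchar(trimws(nm))) {
      stop("category ", i, ": missing or empty `name`", call. = FALSE)
    }
    tier <- cat_i$tier
    if (is.null(tier) || length(tier) != 1L || !(tier %in% c(1, 2))) {
      stop("category \"", nm, "\": `tier` must be 1 or 2", call. = FALSE)
    }
    lits <- as.character(unlist(cat_i$literals, use.names = FALSE))
    rx <- as.character(unlist(cat_i$regexes, use.names = FALSE))
    if (length(lits) + length(rx) == 0L) {
      stop("category \"", nm, "\": no entries (needs at least one literal or regex)",
           call. = FALSE)
    }
    list(name = nm, tier = as.integer(tier), literals = lits, regexes = rx)
  })
  nms <- vapply(categories, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate category name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  if (!is.character(version) || length(version) != 1L) {
    stop("`version` must be a single string", call. = FALSE)
  }
  structure(list(version = version, categories = categories),
            class = "sleep_vocabulary")
}

#' Load a keyword vocabulary
#'
#' Reads the packaged DSE bank (`source = "dse"`) or a user vocabulary file
#' in the same JSON schema: an object with a `version` string and a
#' `categories` array of `{name, tier, literals[], regexes[]}` records.
#' All regex entries must compile; empty entries and malformed records are
#' rejected with an error naming the offending category.
#'
#' @param source Either the builtin identifier `"dse"` or a path to a
#'   vocabulary JSON file.
#' @return A validated `sleep_vocabulary` object.
#' @examples
#' v <- load_vocabulary("dse")
#' vocab_stats(v)
#' @export
load_vocabulary <- function(source = "dse") {
  if (!is.character(source) || length(source) != 1L || !nzchar(source)) {
    stop("`source` must be \"dse\" or a file path", call. = FALSE)
  }
  path <- if (identical(source, "dse")) {
    system.file("extdata", "dse_vocabulary.json", package = "pedsleepnlp",
                mustWork = TRUE)
  } else {
    if (!file.exists(source)) stop("vocabulary file not found: ", source, call. = FALSE)
    source
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed vocabulary file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(parsed$categories) || length(parsed$categories) == 0L) {
    stop("vocabulary file ", path, " defines no categories", call. = FALSE)
  }
  v <- vocabulary(parsed$categories,
                  version = if (is.null(parsed$version)) "unversioned" else parsed$version)
  rep <- validate_vocabulary(v)
  fatal <- rep[rep$level == "fatal", , drop = FALSE]
  if (nrow(fatal) > 0L) {
    stop("invalid vocabulary (", path, "): ",
         paste(fatal$message, collapse = "; "), call. = FALSE)
  }
  v
}

#' Validate a vocabulary and report findings
#'
#' Produces a finding-per-row report rather than erroring, so informational
#' oddities of a published bank can be surfaced without rejecting it:
#' * `fatal` -- empty entries, non-compiling regexes;
#' * `warning` -- duplicate surfaces within one category (matching no-ops);
#' * `info` -- surfaces shared across categories (legitimate: e.g. the DSE
#'   bank lists "trouble sleeping" under both Sleep quality and Sleep
#'   disturbances, so a hit reports both categories).
#'
#' Duplicates are detected on the normalized token sequence, so "low energy"
#' and "low-energy" count as the same surface.
#'
#' @param v A `sleep_vocabulary` object.
#' @return A tibble with columns `level`, `category`, `surface`, `message`.
#'   Zero rows means a perfectly clean vocabulary.
#' @export
validate_vocabulary <- function(v) {
  stopifnot(inherits(v, "sleep_vocabulary"))
  rows <- list()
  add <- function(level, category, surface, message) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      level = level, category = category, surface = surface, message = message)
  }
  surface_map <- list() # normalized surface key -> character vector of categories
  for (cat_i in v$categories) {
    seen_keys <- character(0)
    for (lit in cat_i$literals) {
      if (!nzchar(trimws(lit))) {
        add("fatal", cat_i$name, lit,
            sprintf("empty literal entry in category \"%s\"", cat_i$name))
        next
      }
      key <- paste(normalize_text(lit)$tokens, collapse = " ")
      if (!nzchar(key)) {
        add("fatal", cat_i$name, lit,
            sprintf("literal \"%s\" in category \"%s\" has no alphanumeric content",
                    lit, cat_i$name))
        next
      }
      if (key %in% seen_keys) {
        add("warning", cat_i$name, lit,
            sprintf("duplicate surface \"%s\" within category \"%s\"", lit, cat_i$name))
      }
      seen_keys <- c(seen_keys, key)
      surface_map[[key]] <- unique(c(surface_map[[key]], cat_i$name))
    }
    for (rx in cat_i$regexes) {
      if (!nzchar(trimws(rx))) {
        add("fatal", cat_i$name, rx,
            sprintf("empty regex entry in category \"%s\"", cat_i$name))
        next
      }
      ok <- tryCatch({ grepl(rx, "", perl = TRUE); TRUE },
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) {
        add("fatal", cat_i$name, rx,
            sprintf("regex \"%s\" in category \"%s\" does not compile", rx, cat_i$name))
      }
    }
  }
  for (key in names(surface_map)) {
    cats <- surface_map[[key]]
    if (length(cats) > 1L) {
      add("info", paste(cats, collapse = " | "), key,
          sprintf("surface \"%s\" appears in %d categories (%s)",
                  key, length(cats), paste(cats, collapse = ", ")))
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(level = character(0), category = character(0),
                          surface = character(0), message = character(0)))
  }
  do.call(rbind, rows)
}

#' Summary counts for a vocabulary
#'
#' @param v A `sleep_vocabulary` object.
#' @return An object of class `vocab_stats`: a list with
#'   `n_categories_total`, `n_categories_tier1`, `n_categories_tier2`,
#'   `n_literals`, `n_regexes`, and `per_category_counts` (named integer
#'   vector of entries per category, literals + regexes).
#' @export
vocab_stats <- function(v) {
  stopifnot(inherits(v, "sleep_vocabulary"))
  tiers <- vapply(v$categories, `[[`, integer(1), "tier")
  n_lit <- vapply(v$categories, function(ct) length(ct$literals), integer(1))
  n_rx <- vapply(v$categories, function(ct) length(ct$regexes), integer(1))
  per <- n_lit + n_rx
  names(per) <- vapply(v$categories, `[[`, character(1), "name")
  structure(list(
    n_categories_total = length(v$categories),
    n_categories_tier1 = sum(tiers == 1L),
    n_categories_tier2 = sum(tiers == 2L),
    n_literals = sum(n_lit),
    n_regexes = sum(n_rx),
    per_category_counts = per
  ), class = "vocab_stats")
}

#' @export
print.vocab_stats <- function(x, ...) {
  cat("Vocabulary: ", x$n_categories_total, " categories (",
      x$n_categories_tier1, " tier-1, ", x$n_categories_tier2, " tier-2); ",
      x$n_literals, " literals + ", x$n_regexes, " regexes\n", sep = "")
  invisible(x)
}

#' @export
print.sleep_vocabulary <- function(x, ...) {
  cat("<sleep_vocabulary> version \"", x$version, "\"\n", sep = "")
  print(vocab_stats(x))
  invisible(x)
}

#' Write a vocabulary to its canonical JSON form
#'
#' Serialization is canonical (fixed field order, 2-space pretty printing),
#' so `save_vocabulary()` followed by [load_vocabulary()] round-trips the
#' structural content exactly, and saving the same vocabulary twice yields
#' byte-identical files.
#'
#' @param v A `sleep_vocabulary` object.
#' @param dest Output file path.
#' @return `dest`, invisibly.
#' @export
save_vocabulary <- function(v, dest) {
  stopifnot(inherits(v, "sleep_vocabulary"))
  if (!is.character(dest) || length(dest) != 1L || !nzchar(dest)) {
    stop("`dest` must be a non-empty file path", call. = FALSE)
  }
  payload <- list(
    version = jsonlite::unbox(v$version),
    categories = lapply(v$categories, function(ct) {
      list(name = jsonlite::unbox(ct$name),
           tier = jsonlite::unbox(ct$tier),
           literals = as.character(ct$literals),
           regexes = as.character(ct$regexes))
    })
  )
  json <- jsonlite::toJSON(payload, pretty = 2, auto_unbox = FALSE)
  con <- tryCatch(file(dest, open = "wb"),
                  error = function(e) stop("cannot write vocabulary to ", dest,
                                           ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeBin(charToRaw(paste0(as.character(json), "\n")), con)
  invisible(dest)
}

#' The nine annotation dimensions of pediatric sleep health
#'
#' Six sleep-health dimensions (behavior, satisfaction, alertness/daytime
#' sleepiness, timing, efficiency, duration) plus three related clinical
#' concepts (medication, disorder, intervention) used to tag gold-standard
#' annotation spans.
#'
#' @return Character vector of the nine canonical dimension identifiers.
#' @export
sleep_dimensions <- function() {
  c("sleep_behavior", "sleep_satisfaction", "alertness_daytime_sleepiness",
    "sleep_timing", "sleep_efficiency", "sleep_duration",
    "sleep_medication", "sleep_disorder", "sleep_intervention")
}
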