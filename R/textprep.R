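# Text normalization with exact raw-offset bookkeeping.
#
# All matching in this package happens on a normalized token stream; every
# token remembers the half-open [start, end) character interval it came from
# in the raw note, so matches and annotations can always be expressed in raw
# coordinates. Character offsets are 0-based half-open throughout; token
# indices in the R API are 1-based.

# Curly apostrophes/quotes and typographic dashes folded to ASCII 1:1, so
# character offsets never move.
.fold_from <- "‘’‛′“”–—‐‑‒―−"
.fold_to   <- "''''\"\"-------"

#' Normalize raw note text into a matchable token stream
#'
#' Lowercases (ASCII case folding), folds typographic apostrophes, quotes and
#' dashes to their ASCII equivalents, and splits the text on every maximal run
#' of non-alphanumeric characters. Any character outside `[a-z0-9]` after
#' folding -- punctuation, whitespace, and non-ASCII letters alike -- acts as
#' a token boundary. Each token records the half-open `[start, end)` interval
#' it occupies in `raw`, using 0-based character offsets, so downstream
#' matches can be reported in raw coordinates.
#'
#' The boundary rule gives whole-word matching semantics: "nap" never matches
#' inside "naproxen", and "low-energy" tokenizes identically to "low energy".
#'
#' @param raw A single character string (any length, any Unicode).
#' @return An object of class `normalized_text`: a list with elements
#'   `raw` (the input), `tokens` (character vector of lowercase alphanumeric
#'   tokens), `start` and `end` (integer vectors of 0-based half-open
#'   character offsets into `raw`, parallel to `tokens`).
#' @examples
#' nt <- normalize_text("Can’t Sleep!!")
#' nt$tokens # "can" "t" "sleep"
#' @export
normalize_text <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single non-NA character string", call. = FALSE)
  }
  folded <- chartr(.fold_from, .fold_to, raw)
  low <- chartr("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "abcdefghijklmnopqrstuvwxyz", folded)
  m <- gregexpr("[a-z0-9]+", low)[[1L]]
  if (m[1L] == -1L) {
    tokens <- character(0)
    start <- end <- integer(0)
  } else {
    len <- attr(m, "match.length")
    start <- as.integer(m) - 1L
    end <- start + as.integer(len)
    tokens <- substring(low, as.integer(m), as.integer(m) + len - 1L)
  }
  structure(list(raw = raw, tokens = tokens, start = start, end = end),
            class = "normalized_text")
}

#' @export
print.normalized_text <- function(x, ...) {
  cat("<normalized_text> ", length(x$tokens), " token(s) over ",
      nchar(x$raw), " character(s)\n", sep = "")
  if (length(x$tokens)) {
    utils::head(data.frame(token = x$tokens, start = x$start, end = x$end), 10L) |>
      print(row.names = FALSE)
    if (length(x$tokens) > 10L) cat("...\n")
  }
  invisible(x)
}

#' Map a token span back to raw character coordinates
#'
#' @param nt A `normalized_text` object from [normalize_text()].
#' @param first_token,last_token 1-based token indices with
#'   `first_token <= last_token`.
#' @return Integer vector `c(start, end)`: the 0-based half-open character
#'   interval running from the start of the first token to the end of the
#'   last token in `nt$raw`.
#' @export
token_span_to_raw <- function(nt, first_token, last_token) {
  stopifnot(inherits(nt, "normalized_text"))
  n <- length(nt$tokens)
  if (!is.numeric(first_token) || !is.numeric(last_token) ||
      first_token < 1L || last_token > n || first_token > last_token) {
    stop("token indices out of range: need 1 <= first_token <= last_token <= ",
         n, call. = FALSE)
  }
  c(start = nt$start[[first_token]], end = nt$end[[last_token]])
}

# Internal: slice raw text by a 0-based half-open interval.
slice_raw <- function(raw, start, end) substring(raw, start + 1L, end)
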