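# Multi-pattern whole-word matching.
#
# Literal phrases are matched on the normalized token stream with a token
# trie scanned greedily (longest match at the leftmost position, then resume
# after it), the resolution rule of trie-based keyword extractors: nested
# surfaces such as "falling asleep" inside "difficulty falling asleep" are
# reported once, as the longer phrase. Regular-expression entries run
# independently on the space-joined token string and may overlap literal
# hits; after normalization "\d+" can only consume one all-digit token and
# "\w+" one token, which is the intended semantics of the bank's patterns.
#
# A deliberately naive per-entry scanner (`find_matches_bruteforce`) serves
# as the independent oracle the trie matcher is tested against.

#' Compile a vocabulary into a multi-pattern matcher
#'
#' Tokenizes every literal entry with [normalize_text()] and inserts it into
#' a token trie; duplicate surfaces (within or across categories, including
#' spelling variants that normalize identically such as "low energy" /
#' "low-energy") are merged with the union of their categories. Regex entries
#' are de-duplicated by pattern source and kept with their category
#' annotations. Compilation is a pure function of the vocabulary: compiling
#' twice yields matchers with identical behavior.
#'
#' @param v A `sleep_vocabulary` object.
#' @return An object of class `sleep_matcher`.
#' @examples
#' m <- compile_matcher(load_vocabulary("dse"))
#' find_matches(m, "Mom says he snores loudly most nights.")
#' @export
compile_matcher <- function(v) {
  stopifnot(inherits(v, "sleep_vocabulary"))
  rep <- validate_vocabulary(v)
  if (any(rep$level == "fatal")) {
    stop("vocabulary has fatal validation findings; see validate_vocabulary()",
         call. = FALSE)
  }
  surf_cats <- list() # surface key -> data.frame(category, tier)
  for (cat_i in v$categories) {
    for (lit in cat_i$literals) {
      key <- paste(normalize_text(lit)$tokens, collapse = " ")
      cur <- surf_cats[[key]]
      nxt <- data.frame(category = cat_i$name, tier = cat_i$tier,
                        stringsAsFactors = FALSE)
      surf_cats[[key]] <- if (is.null(cur)) nxt else unique(rbind(cur, nxt))
    }
  }
  surfaces <- names(surf_cats)
  trie <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in seq_along(surfaces)) {
    toks <- strsplit(surfaces[[k]], " ", fixed = TRUE)[[1L]]
    node <- trie
    for (tk in toks) {
      nxt <- get0(tk, envir = node, inherits = FALSE)
      if (is.null(nxt)) {
        nxt <- new.env(parent = emptyenv(), hash = TRUE)
        assign(tk, nxt, envir = node)
      }
      node <- nxt
    }
    assign(".term", k, envir = node)
  }
  rx_cats <- list() # pattern source -> data.frame(category, tier)
  for (cat_i in v$categories) {
    for (rx in cat_i$regexes) {
      cur <- rx_cats[[rx]]
      nxt <- data.frame(category = cat_i$name, tier = cat_i$tier,
                        stringsAsFactors = FALSE)
      rx_cats[[rx]] <- if (is.null(cur)) nxt else unique(rbind(cur, nxt))
    }
  }
  rx_src <- names(rx_cats)
  structure(list(
    trie = trie,
    surfaces = surfaces,
    surface_cats = unname(surf_cats),
    regex_src = if (is.null(rx_src)) character(0) else rx_src,
    regex_wrapped = vapply(if (is.null(rx_src)) character(0) else rx_src,
                           function(s) paste0("(?<![a-z0-9])(?:", s, ")(?![a-z0-9])"),
                           character(1), USE.NAMES = FALSE),
    regex_cats = unname(rx_cats),
    vocab_version = v$version
  ), class = "sleep_matcher")
}

#' @export
print.sleep_matcher <- function(x, ...) {
  cat("<sleep_matcher> ", length(x$surfaces), " literal surfaces, ",
      length(x$regex_src), " regex patterns (vocabulary \"",
      x$vocab_version, "\")\n", sep = "")
  invisible(x)
}

empty_matches <- function() {
  tibble::tibble(start = integer(0), end = integer(0), text = character(0),
                 surface = character(0), kind = character(0),
                 category = character(0), tier = integer(0))
}

# Canonical ordering + (span, category) de-duplication shared by both
# matching routes so their outputs are directly comparable.
finalize_matches <- function(df) {
  if (nrow(df) == 0L) return(empty_matches())
  df <- unique(df)
  df <- df[order(df$start, df$end, df$kind, df$surface, df$category), ,
           drop = FALSE]
  tibble::as_tibble(df, .name_repair = "minimal")
}

# Map regex hits on the space-joined token string back to raw offsets and
# emit one row per (hit, category). `joined` positions are 1-based; token k
# occupies [tok_pos[k], tok_pos[k] + nchar(token k) - 1].
regex_match_rows <- function(nt, joined, tok_pos, wrapped, src, cats_df) {
  hits <- gregexpr(wrapped, joined, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(NULL)
  lens <- attr(hits, "match.length")
  out <- vector("list", length(hits))
  for (h in seq_along(hits)) {
    s <- as.integer(hits[[h]]); e <- s + lens[[h]] - 1L
    first_tok <- findInterval(s, tok_pos)
    last_tok <- findInterval(e, tok_pos)
    raw_start <- nt$start[[first_tok]]
    raw_end <- nt$end[[last_tok]]
    out[[h]] <- data.frame(
      start = raw_start, end = raw_end,
      text = slice_raw(nt$raw, raw_start, raw_end),
      surface = src, kind = "regex",
      category = cats_df$category, tier = cats_df$tier,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Find all keyword and regex matches in a note
#'
#' Literal matches are resolved longest-leftmost and non-overlapping among
#' themselves; regex matches are enumerated independently and may overlap
#' literal hits (their categories differ, and span-coverage analysis wants
#' completeness). A surface listed under several categories yields one row
#' per category at the same span.
#'
#' @param m A `sleep_matcher` from [compile_matcher()].
#' @param raw Note text (single string).
#' @return A tibble with one row per (match span, category): `start`, `end`
#'   (0-based half-open raw character offsets), `text` (raw slice),
#'   `surface` (normalized entry surface, or pattern source for regex hits),
#'   `kind` (`"literal"` or `"regex"`), `category`, `tier`. Sorted by
#'   `start`, then `end`; exact (span, category) duplicates removed.
#' @export
find_matches <- function(m, raw) {
  stopifnot(inherits(m, "sleep_matcher"))
  nt <- normalize_text(raw)
  n <- length(nt$tokens)
  rows <- list()
  if (n > 0L) {
    toks <- nt$tokens
    i <- 1L
    while (i <= n) {
      node <- m$trie
      j <- i
      best_end <- 0L
      best_key <- 0L
      while (j <= n) {
        node <- get0(toks[[j]], envir = node, inherits = FALSE)
        if (is.null(node)) break
        term <- get0(".term", envir = node, inherits = FALSE)
        if (!is.null(term)) {
          best_end <- j
          best_key <- term
        }
        j <- j + 1L
      }
      if (best_key > 0L) {
        cats <- m$surface_cats[[best_key]]
        raw_start <- nt$start[[i]]
        raw_end <- nt$end[[best_end]]
        rows[[length(rows) + 1L]] <- data.frame(
          start = raw_start, end = raw_end,
          text = slice_raw(nt$raw, raw_start, raw_end),
          surface = m$surfaces[[best_key]], kind = "literal",
          category = cats$category, tier = cats$tier,
          stringsAsFactors = FALSE)
        i <- best_end + 1L
      } else {
        i <- i + 1L
      }
    }
    if (length(m$regex_src) > 0L) {
      joined <- paste(toks, collapse = " ")
      tok_pos <- cumsum(c(1L, utils::head(nchar(toks), -1L) + 1L))
      for (r in seq_along(m$regex_src)) {
        rr <- regex_match_rows(nt, joined, tok_pos, m$regex_wrapped[[r]],
                               m$regex_src[[r]], m$regex_cats[[r]])
        if (!is.null(rr)) rows[[length(rows) + 1L]] <- rr
      }
    }
  }
  if (length(rows) == 0L) return(empty_matches())
  finalize_matches(do.call(rbind, rows))
}

# Parse a token-element regex pattern ("less than \d+ hours") into per-token
# matcher functions. Elements are space-separated; "\d+" matches one
# all-digit token, "\w+" any one token, anything else is anchored as a
# whole-token regex. Fixed window length = number of elements.
parse_token_pattern <- function(src) {
  elems <- strsplit(src, " ", fixed = TRUE)[[1L]]
  elems <- elems[nzchar(elems)]
  lapply(elems, function(el) {
    if (identical(el, "\\d+")) {
      function(tok) grepl("^[0-9]+$", tok)
    } else if (identical(el, "\\w+")) {
      function(tok) TRUE
    } else {
      force(el)
      function(tok) grepl(paste0("^(?:", el, ")$"), tok, perl = TRUE)
    }
  })
}

#' Brute-force reference matcher (testing oracle)
#'
#' Scans the normalized token sequence for every vocabulary entry
#' independently -- no trie, no shared state -- then applies the same
#' longest-leftmost non-overlapping resolution to the literal candidates.
#' Regex entries are interpreted as space-separated token elements and slid
#' over fixed-length token windows. By contract the output equals
#' [find_matches()] on every input; the test suite enforces this on seeded
#' random corpora.
#'
#' Supports the packaged bank and any vocabulary whose regexes are
#' space-separated token elements (literal words, `\d+`, `\w+`).
#'
#' @param v A `sleep_vocabulary` object.
#' @param raw Note text (single string).
#' @return Same shape as [find_matches()].
#' @export
find_matches_bruteforce <- function(v, raw) {
  stopifnot(inherits(v, "sleep_vocabulary"))
  nt <- normalize_text(raw)
  n <- length(nt$tokens)
  if (n == 0L) return(empty_matches())
  toks <- nt$tokens

  # surface key -> categories (independent tally, same merge rule)
  surf_cats <- list()
  rx_cats <- list()
  for (cat_i in v$categories) {
    for (lit in cat_i$literals) {
      key <- paste(normalize_text(lit)$tokens, collapse = " ")
      cur <- surf_cats[[key]]
      nxt <- data.frame(category = cat_i$name, tier = cat_i$tier,
                        stringsAsFactors = FALSE)
      surf_cats[[key]] <- if (is.null(cur)) nxt else unique(rbind(cur, nxt))
    }
    for (rx in cat_i$regexes) {
      cur <- rx_cats[[rx]]
      nxt <- data.frame(category = cat_i$name, tier = cat_i$tier,
                        stringsAsFactors = FALSE)
      rx_cats[[rx]] <- if (is.null(cur)) nxt else unique(rbind(cur, nxt))
    }
  }

  # every literal candidate (token ranges), one entry at a time
  cand <- list()
  for (key in names(surf_cats)) {
    etoks <- strsplit(key, " ", fixed = TRUE)[[1L]]
    L <- length(etoks)
    if (L > n) next
    starts <- which(toks == etoks[[1L]])
    starts <- starts[starts + L - 1L <= n]
    for (s in starts) {
      if (L == 1L || all(toks[s:(s + L - 1L)] == etoks)) {
        cand[[length(cand) + 1L]] <- list(tstart = s, tend = s + L - 1L, key = key)
      }
    }
  }
  rows <- list()
  if (length(cand) > 0L) {
    tstart <- vapply(cand, `[[`, integer(1), "tstart")
    tend <- vapply(cand, `[[`, integer(1), "tend")
    # longest-leftmost greedy: at each scan position take the candidate
    # starting there with the greatest extent, then jump past it
    i <- 1L
    while (i <= n) {
      here <- which(tstart == i)
      if (length(here) > 0L) {
        pick <- here[[which.max(tend[here])]]
        key <- cand[[pick]]$key
        cats <- surf_cats[[key]]
        raw_start <- nt$start[[i]]
        raw_end <- nt$end[[tend[[pick]]]]
        rows[[length(rows) + 1L]] <- data.frame(
          start = raw_start, end = raw_end,
          text = slice_raw(nt$raw, raw_start, raw_end),
          surface = key, kind = "literal",
          category = cats$category, tier = cats$tier,
          stringsAsFactors = FALSE)
        i <- tend[[pick]] + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  # regexes: fixed-length token windows, enumerated left to right without
  # overlap per pattern (mirrors consecutive regex scanning)
  for (src in names(rx_cats)) {
    elems <- parse_token_pattern(src)
    L <- length(elems)
    if (L == 0L || L > n) next
    cats <- rx_cats[[src]]
    s <- 1L
    while (s + L - 1L <= n) {
      window <- toks[s:(s + L - 1L)]
      ok <- all(vapply(seq_len(L), function(k) elems[[k]](window[[k]]), logical(1)))
      if (ok) {
        raw_start <- nt$start[[s]]
        raw_end <- nt$end[[s + L - 1L]]
        rows[[length(rows) + 1L]] <- data.frame(
          start = raw_start, end = raw_end,
          text = slice_raw(nt$raw, raw_start, raw_end),
          surface = src, kind = "regex",
          category = cats$category, tier = cats$tier,
          stringsAsFactors = FALSE)
        s <- s + L
      } else {
        s <- s + 1L
      }
    }
  }
  if (length(rows) == 0L) return(empty_matches())
  finalize_matches(do.call(rbind, rows))
}
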