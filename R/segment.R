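#' Default rule-based sentence splitter
#'
#' Splits on runs of terminal punctuation (`.`, `!`, `?`) followed by
#' whitespace or end of text, except when the preceding word is a known
#' abbreviation or a single-letter initial. Deterministic; used throughout
#' the test suite. Any `function(body) -> tibble(start, end)` with 0-based
#' half-open character spans can be substituted.
#'
#' @param body Character scalar.
#' @return A tibble with integer columns `start` and `end` (0-based,
#'   half-open offsets into `body`), one row per sentence, in order.
#' @export
split_sentences_default <- function(body) {
  empty <- tibble::tibble(start = integer(0), end = integer(0))
  if (is.na(body) || !nzchar(trimws(body))) return(empty)
  abbrev <- c("mr", "mrs", "ms", "dr", "prof", "st", "vs", "etc", "no", "jr",
              "sr", "inc", "ltd", "fig", "al", "eg", "ie", "approx", "gen",
              "gov", "sen", "rep", "col", "capt", "lt")
  m <- gregexpr("[.!?]+(\\s+|$)", body, perl = TRUE)[[1]]
  cut_after <- integer(0)  # 1-based index of last char belonging to a sentence
  if (m[1] != -1) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      punct_run <- regmatches(body, list(m))[[1]][k]
      punct_len <- nchar(sub("\\s+$", "", punct_run))
      punct_end <- starts[k] + punct_len - 1L
      # word immediately before the punctuation
      before <- substr(body, max(1L, starts[k] - 20L), starts[k] - 1L)
      last_word <- tolower(sub(".*?([A-Za-z]+)$", "\\1", before))
      if (grepl("[A-Za-z]$", before) &&
          (last_word %in% abbrev || nchar(last_word) == 1L) &&
          substr(body, starts[k], starts[k]) == ".") {
        next  # abbreviation or initial: not a sentence boundary
      }
      cut_after <- c(cut_after, punct_end)
    }
  }
  n <- nchar(body)
  if (length(cut_after) == 0 || max(cut_after) < n) {
    if (nzchar(trimws(substr(body, if (length(cut_after)) max(cut_after) + 1L else 1L, n)))) {
      cut_after <- c(cut_after, n)
    }
  }
  begin <- 1L
  spans <- vector("list", length(cut_after))
  for (k in seq_along(cut_after)) {
    s <- begin
    while (s <= cut_after[k] && grepl("^\\s$", substr(body, s, s))) s <- s + 1L
    e <- cut_after[k]
    while (e >= s && grepl("^\\s$", substr(body, e, e))) e <- e - 1L
    if (e >= s) spans[[k]] <- c(s - 1L, e)  # to 0-based half-open
    begin <- cut_after[k] + 1L
  }
  spans <- spans[!vapply(spans, is.null, logical(1))]
  tibble::tibble(
    start = vapply(spans, `[`, integer(1), 1L),
    end   = vapply(spans, `[`, integer(1), 2L)
  )
}

#' Segment one article body into sentences
#'
#' @param article One-row corpus tibble (or a list with `article_id`, `body`).
#' @param splitter Pluggable segmentation function; default
#'   [split_sentences_default()].
#' @return A sentence-index tibble with columns `article_id`, `sentence`
#'   (0-based position), `start`, `end` (0-based half-open offsets into the
#'   body) and `text` (the exact substring). Empty body gives zero rows.
#' @export
segment_sentences <- function(article, splitter = split_sentences_default) {
  body <- article$body[[1]]
  id <- article$article_id[[1]]
  spans <- splitter(body)
  stopifnot(is.data.frame(spans), all(c("start", "end") %in% names(spans)))
  if (nrow(spans) > 0) {
    if (any(spans$end <= spans$start) || any(spans$start < 0) ||
        any(spans$end > nchar(body))) {
      validation_error("Splitter returned spans outside body bounds for article '%s'", id)
    }
    if (is.unsorted(spans$start, strictly = TRUE) ||
        any(utils::head(spans$end, -1) > utils::tail(spans$start, -1))) {
      validation_error("Splitter returned overlapping or unordered spans for article '%s'", id)
    }
  }
  txt <- if (nrow(spans) > 0) substring(body, spans$start + 1L, spans$end) else character(0)
  tibble::tibble(
    article_id = rep(id, nrow(spans)),
    sentence = seq_len(nrow(spans)) - 1L,
    start = as.integer(spans$start),
    end = as.integer(spans$end),
    text = txt
  )
}

#' Segment every article in a corpus
#'
#' @param corpus A corpus tibble.
#' @param splitter Pluggable segmentation function.
#' @return One sentence-index tibble covering all articles (see
#'   [segment_sentences()]).
#' @export
segment_corpus <- function(corpus, splitter = split_sentences_default) {
  if (nrow(corpus) == 0) {
    return(tibble::tibble(article_id = character(0), sentence = integer(0),
                          start = integer(0), end = integer(0), text = character(0)))
  }
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    segment_sentences(corpus[i, , drop = FALSE], splitter = splitter)
  })
}
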