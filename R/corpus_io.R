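#' Read a news corpus from JSONL or CSV
#'
#' A corpus is a tibble with one row per article and columns `article_id`,
#' `title`, `body`, `source`, `published_at` (Date), `country_tags`
#' (list-column of country codes) and `language`. In JSONL each line is one
#' JSON object with those fields (`country_tags` as an array, `published_at`
#' ISO-8601); in CSV `country_tags` is pipe-delimited.
#'
#' Records missing `article_id` or with an empty `title` are rejected: the
#' error names the offending record number and field, because the title is the
#' deduplication key and ids must be unique.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return A corpus tibble with a `source_path` attribute.
#' @seealso [write_corpus()], [deduplicate_by_title()], [filter_language()]
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Cannot read corpus: file '%s' does not exist", path),
          class = "newswatch_io_error")
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    records <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) {
        validation_error("Malformed JSON at record %d: %s", i, conditionMessage(e))
      })
      rec
    })
    corpus <- tibble::tibble(
      article_id   = vapply(records, function(r) as.character(r$article_id %||% NA_character_), character(1)),
      title        = vapply(records, function(r) as.character(r$title %||% NA_character_), character(1)),
      body         = vapply(records, function(r) as.character(r$body %||% ""), character(1)),
      source       = vapply(records, function(r) as.character(r$source %||% NA_character_), character(1)),
      published_at = as.Date(vapply(records, function(r) as.character(r$published_at %||% NA_character_), character(1))),
      country_tags = lapply(records, function(r) as.character(unlist(r$country_tags))),
      language     = vapply(records, function(r) as.character(r$language %||% "unknown"), character(1))
    )
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    needed <- c("article_id", "title", "body", "source", "published_at",
                "country_tags", "language")
    missing_cols <- setdiff(needed, names(df))
    if (length(missing_cols) > 0) {
      validation_error("CSV corpus missing column(s): %s",
                       paste(missing_cols, collapse = ", "))
    }
    corpus <- tibble::tibble(
      article_id   = as.character(df$article_id),
      title        = as.character(df$title),
      body         = as.character(df$body),
      source       = as.character(df$source),
      published_at = as.Date(df$published_at),
      country_tags = strsplit(ifelse(is.na(df$country_tags), "", df$country_tags), "\\|"),
      language     = as.character(df$language)
    )
    corpus$country_tags <- lapply(corpus$country_tags, function(x) x[nzchar(x)])
  }
  validate_corpus(corpus)
  attr(corpus, "source_path") <- path
  corpus
}

#' Validate corpus invariants
#'
#' Checks that every record has a non-empty unique `article_id` and a
#' non-empty `title`; failures are reported per record.
#'
#' @param corpus A corpus tibble.
#' @return The corpus, invisibly, if valid.
#' @export
validate_corpus <- function(corpus) {
  bad_id <- which(is.na(corpus$article_id) | !nzchar(corpus$article_id))
  if (length(bad_id) > 0) {
    validation_error("Record %d: missing or empty field 'article_id'", bad_id[1])
  }
  bad_title <- which(is.na(corpus$title) | !nzchar(trimws(corpus$title)))
  if (length(bad_title) > 0) {
    validation_error("Record %d: missing or empty field 'title'", bad_title[1])
  }
  dup <- corpus$article_id[duplicated(corpus$article_id)]
  if (length(dup) > 0) {
    validation_error("Duplicate article_id in corpus: '%s'", dup[1])
  }
  invisible(corpus)
}

#' Write a corpus to JSONL or CSV
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, f))` returns `x`
#' (row order preserved).
#'
#' @param corpus A corpus tibble.
#' @param path Output path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(list(
        article_id   = corpus$article_id[i],
        title        = corpus$title[i],
        body         = corpus$body[i],
        source       = corpus$source[i],
        published_at = format(corpus$published_at[i], "%Y-%m-%d"),
        country_tags = corpus$country_tags[[i]],
        language     = corpus$language[i]
      ), auto_unbox = TRUE, null = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- corpus
    df$country_tags <- vapply(corpus$country_tags, paste, character(1), collapse = "|")
    df$published_at <- format(corpus$published_at, "%Y-%m-%d")
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Remove duplicate articles by title
#'
#' Keeps at most one article per (normalized) title. The surviving
#' representative is the earliest by `published_at`, with ties broken by first
#' appearance in the corpus, so the result is deterministic. The number of
#' removed articles is recorded in the `n_removed` attribute and reported via
#' a message.
#'
#' @param corpus A corpus tibble.
#' @param normalization `"casefold_trim"` (default: lowercase and trim
#'   whitespace before comparing) or `"exact"`.
#' @return The deduplicated corpus, in original row order.
#' @export
deduplicate_by_title <- function(corpus, normalization = c("casefold_trim", "exact")) {
  normalization <- match.arg(normalization)
  if (nrow(corpus) == 0) return(corpus)
  key <- if (normalization == "casefold_trim") {
    trimws(tolower(corpus$title))
  } else {
    corpus$title
  }
  ord <- order(xtfrm(corpus$published_at), seq_len(nrow(corpus)), na.last = TRUE)
  keep_ids <- corpus$article_id[ord][!duplicated(key[ord])]
  out <- corpus[corpus$article_id %in% keep_ids, , drop = FALSE]
  n_removed <- nrow(corpus) - nrow(out)
  attr(out, "n_removed") <- n_removed
  inform(sprintf("deduplicate_by_title: removed %d duplicate article(s), %d remain",
                 n_removed, nrow(out)))
  out
}

#' Built-in English language detector
#'
#' A deterministic function-word detector: text is labelled `"en"` when at
#' least `min_hits` common English function words occur among its tokens, and
#' `"unknown"` otherwise. It is the packaged default for the pluggable
#' detector contract of [filter_language()]; swap in any `function(text)`
#' returning a 2-letter code for production use.
#'
#' @param text Character scalar.
#' @param min_hits Minimum number of function-word token hits (default 2).
#' @return `"en"` or `"unknown"`.
#' @export
detect_language_en <- function(text, min_hits = 2L) {
  fw <- c("the", "of", "and", "to", "in", "a", "is", "that", "for", "it",
          "on", "was", "with", "as", "at", "by", "from", "are", "this", "an",
          "be", "have", "has", "were", "will", "their", "said")
  toks <- tokenize1(text)
  if (sum(toks %in% fw) >= min_hits) "en" else "unknown"
}

#' Keep only articles in one language
#'
#' Applies a deterministic, pluggable text-to-language detector to
#' `title + body` of every article and retains the articles whose detected
#' language equals `keep`. Articles for which the detector errors are flagged
#' `unknown` and dropped with a warning. The fraction retained is reported.
#'
#' @param corpus A corpus tibble.
#' @param detector `function(text) -> language code`; default
#'   [detect_language_en()].
#' @param keep Language code to retain (default `"en"`).
#' @return The filtered corpus with a `fraction_retained` attribute; the
#'   `language` column is updated to the detected codes.
#' @export
filter_language <- function(corpus, detector = detect_language_en, keep = "en") {
  if (nrow(corpus) == 0) {
    attr(corpus, "fraction_retained") <- NA_real_
    return(corpus)
  }
  detected <- vapply(seq_len(nrow(corpus)), function(i) {
    tryCatch(
      as.character(detector(paste(corpus$title[i], corpus$body[i]))),
      error = function(e) {
        warn(sprintf("language detector failed on article '%s'; flagged unknown",
                     corpus$article_id[i]))
        "unknown"
      })
  }, character(1))
  corpus$language <- detected
  out <- corpus[detected == keep, , drop = FALSE]
  frac <- nrow(out) / nrow(corpus)
  attr(out, "fraction_retained") <- frac
  inform(sprintf("filter_language: retained %d/%d articles (%.1f%%) in '%s'",
                 nrow(out), nrow(corpus), 100 * frac, keep))
  out
}
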