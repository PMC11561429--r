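#' Load a country gazetteer
#'
#' A gazetteer maps canonical country codes to their surface names (official
#' name plus common aliases). Every surface name must map to exactly one
#' code. The packaged default is a hand-built ISO-3166 subset shipped as
#' plain CSV (`code,name,aliases`, aliases pipe-delimited).
#'
#' @param path Path to a gazetteer CSV; `NULL` (default) loads the packaged
#'   file.
#' @return A tibble with columns `code`, `name` (canonical) and `surface`
#'   (one row per surface name).
#' @export
load_gazetteer <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "country_gazetteer.csv", package = "newswatch")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(df)), function(i) {
    aliases <- if (is.na(df$aliases[i]) || !nzchar(df$aliases[i])) character(0) else
      strsplit(df$aliases[i], "\\|")[[1]]
    tibble::tibble(code = df$code[i], name = df$name[i],
                   surface = c(df$name[i], aliases))
  })
  dup <- tolower(rows$surface)[duplicated(tolower(rows$surface))]
  if (length(dup) > 0) {
    validation_error("gazetteer surface name '%s' maps to more than one code", dup[1])
  }
  rows
}

# count contiguous occurrences of a tokenized phrase in a token vector,
# returning count and 1-based position of the first occurrence (NA if none)
phrase_occurrences <- function(phrase_tokens, tokens) {
  np <- length(phrase_tokens)
  nt <- length(tokens)
  if (np == 0 || nt < np) return(list(count = 0L, first = NA_integer_))
  starts <- which(tokens == phrase_tokens[1])
  starts <- starts[starts + np - 1L <= nt]
  hits <- starts[vapply(starts, function(s) {
    all(tokens[s:(s + np - 1L)] == phrase_tokens)
  }, logical(1))]
  list(count = length(hits), first = if (length(hits)) hits[1] else NA_integer_)
}

#' Count candidate-country mentions in a text
#'
#' Counts token-boundary, case-insensitive occurrences of each candidate
#' country's surface names. Codes never mentioned get count 0.
#'
#' @param text Character scalar.
#' @param gazetteer Tibble from [load_gazetteer()].
#' @param candidates Character vector of candidate country codes (nonempty).
#' @return A tibble with columns `code`, `count` and `first_pos` (token
#'   position of the earliest mention, `NA` when absent), one row per
#'   candidate, in candidate order.
#' @export
extract_country_mentions <- function(text, gazetteer, candidates) {
  if (length(candidates) == 0) validation_error("candidate country set is empty")
  tokens <- tokenize1(text)
  purrr::map_dfr(candidates, function(code) {
    surfaces <- gazetteer$surface[gazetteer$code == code]
    occ <- lapply(nw_tokenize(surfaces), phrase_occurrences, tokens = tokens)
    counts <- vapply(occ, `[[`, integer(1), "count")
    firsts <- vapply(occ, `[[`, integer(1), "first")
    tibble::tibble(code = code, count = sum(counts),
                   first_pos = if (any(!is.na(firsts))) min(firsts, na.rm = TRUE) else NA_integer_)
  })
}

#' Built-in capitalized-sequence entity extractor
#'
#' Extracts maximal runs of capitalized words as candidate named entities
#' (locations, people), in document order. It is the packaged default for the
#' pluggable NER contract of [assign_country()]; substitute any
#' `function(text) -> character vector` (e.g. a dictionary extractor or a
#' model-based NER) for production use.
#'
#' @param text Character scalar.
#' @return Character vector of entity strings in document order.
#' @export
ner_capitalized <- function(text) {
  m <- gregexpr("\\b[A-Z][A-Za-z]+(?:\\s+[A-Z][A-Za-z]+)*", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, list(m))[[1]]
}

#' Cosine similarity of two vectors
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return Value in \eqn{[-1, 1]}.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("cosine_similarity: zero vector (degenerate embedding)",
          class = "newswatch_degenerate_embedding")
  }
  sum(u * v) / (nu * nv)
}

#' Assign one country to an article
#'
#' Resolution order:
#' 1. **Mention frequency** — if any candidate country is mentioned in the
#'    title or the first body sentence, pick the most frequently mentioned
#'    one (ties: earliest first occurrence in title-then-first-sentence
#'    order).
#' 2. **Embedding similarity** — otherwise collect named entities from the
#'    body (pluggable `ner`), concatenate them in document order, encode to
#'    one vector, encode each candidate's canonical name, and pick the
#'    candidate maximizing cosine similarity (ties: lexicographically
#'    smallest code).
#' 3. **Unresolved** — if the body yields no entities, keep the first
#'    candidate tag with method `"unresolved"`.
#'
#' @param article One-row corpus tibble with nonempty `country_tags`.
#' @param sentences Sentence index for the article.
#' @param gazetteer Tibble from [load_gazetteer()].
#' @param encoder Deterministic text encoder (default [hashing_encoder()]).
#' @param ner Entity extractor `function(text) -> character` (default
#'   [ner_capitalized()]).
#' @return A one-row tibble: `article_id`, `country`, `method`
#'   (`mention_frequency`, `embedding_similarity` or `unresolved`), `score`
#'   (mention count or cosine value).
#' @export
assign_country <- function(article, sentences, gazetteer,
                           encoder = hashing_encoder(), ner = ner_capitalized) {
  candidates <- article$country_tags[[1]]
  if (length(candidates) == 0) {
    validation_error("article '%s' has no candidate country tags", article$article_id[[1]])
  }
  first_sentence <- if (nrow(sentences) > 0) sentences$text[[1]] else ""
  head_text <- paste(article$title[[1]], first_sentence)
  mentions <- extract_country_mentions(head_text, gazetteer, candidates)
  if (any(mentions$count > 0)) {
    hit <- mentions[mentions$count > 0, , drop = FALSE]
    hit <- hit[order(-hit$count, hit$first_pos), , drop = FALSE]
    return(tibble::tibble(article_id = article$article_id[[1]],
                          country = hit$code[1],
                          method = "mention_frequency",
                          score = as.numeric(hit$count[1])))
  }
  entities <- ner(article$body[[1]])
  if (length(entities) == 0) {
    return(tibble::tibble(article_id = article$article_id[[1]],
                          country = candidates[1],
                          method = "unresolved", score = NA_real_))
  }
  doc_vec <- encoder(paste(entities, collapse = " "))
  if (sqrt(sum(doc_vec^2)) == 0) {
    return(tibble::tibble(article_id = article$article_id[[1]],
                          country = candidates[1],
                          method = "unresolved", score = NA_real_))
  }
  names_of <- vapply(candidates, function(code) {
    nm <- gazetteer$name[gazetteer$code == code]
    if (length(nm) == 0) code else nm[1]
  }, character(1))
  sims <- vapply(seq_along(candidates), function(j) {
    cv <- encoder(names_of[j])
    if (sqrt(sum(cv^2)) == 0) return(-Inf)
    cosine_similarity(doc_vec, cv)
  }, numeric(1))
  ord <- order(-sims, candidates)
  tibble::tibble(article_id = article$article_id[[1]],
                 country = candidates[ord[1]],
                 method = "embedding_similarity",
                 score = sims[ord[1]])
}

#' Assign countries for a whole corpus
#'
#' @param corpus A corpus tibble.
#' @param sentences Optional precomputed sentence index.
#' @inheritParams assign_country
#' @return A tibble with one row per article: `article_id`, `country`,
#'   `method`, `score`.
#' @export
assign_countries <- function(corpus, sentences = NULL, gazetteer = load_gazetteer(),
                             encoder = hashing_encoder(), ner = ner_capitalized) {
  if (is.null(sentences)) sentences <- segment_corpus(corpus)
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    art <- corpus[i, , drop = FALSE]
    sn <- sentences[sentences$article_id == art$article_id, , drop = FALSE]
    assign_country(art, sn, gazetteer, encoder = encoder, ner = ner)
  })
}
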