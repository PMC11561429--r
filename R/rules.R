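#' Boolean keyword rule predicates
#'
#' Predicates are finite boolean trees evaluated against an article. The leaf
#' `rule_match()` tests whether at least `min_distinct` distinct keyword
#' phrases occur in the chosen scope:
#'
#' * `"title"` — anywhere in the title;
#' * `"body"` — anywhere in the body;
#' * `"sentence"` — at least one single sentence must contain
#'   `min_distinct` distinct phrases on its own; the matching sentences are
#'   recorded (they later serve as topic-focused summarization pseudolabels).
#'
#' Matching is case-insensitive, on token boundaries after punctuation
#' stripping (`"nurse"` does not fire on `"nursery"`), and a multi-token
#' phrase must occur as a contiguous token sequence. "Distinct" counts
#' different phrases, not repeated occurrences of one phrase.
#'
#' `rule_and()` / `rule_or()` combine two or more predicates; `rule_not()`
#' negates one (exclusion rules are expressed as `rule_not(rule_match(...))`).
#'
#' @param scope One of `"title"`, `"body"`, `"sentence"`.
#' @param keywords Character vector of keyword phrases (1+ tokens each);
#'   lowercased on construction; duplicates are an error.
#' @param min_distinct Minimum number of distinct phrases required (default 1).
#' @param ... Two or more child predicates.
#' @param p A predicate to negate.
#' @return An object of class `nw_predicate`.
#' @export
#' @examples
#' rule_and(
#'   rule_match("sentence", c("strike", "walkout")),
#'   rule_not(rule_match("title", "sports"))
#' )
rule_match <- function(scope = c("title", "body", "sentence"), keywords,
                       min_distinct = 1L) {
  scope <- match.arg(scope)
  keywords <- tolower(as.character(keywords))
  if (length(keywords) == 0) validation_error("keyword list must be nonempty")
  if (anyDuplicated(keywords)) {
    validation_error("duplicate keyword phrase: '%s'",
                     keywords[duplicated(keywords)][1])
  }
  min_distinct <- as.integer(min_distinct)
  if (is.na(min_distinct) || min_distinct < 1L) {
    validation_error("min_distinct must be an integer >= 1")
  }
  if (min_distinct > length(keywords)) {
    validation_error("min_distinct (%d) exceeds keyword list size (%d)",
                     min_distinct, length(keywords))
  }
  structure(list(op = "match", scope = scope, keywords = keywords,
                 min_distinct = min_distinct), class = "nw_predicate")
}

#' @rdname rule_match
#' @export
rule_and <- function(...) {
  children <- list(...)
  if (length(children) < 2) validation_error("AND needs at least 2 children")
  stopifnot(all(vapply(children, inherits, logical(1), "nw_predicate")))
  structure(list(op = "and", children = children), class = "nw_predicate")
}

#' @rdname rule_match
#' @export
rule_or <- function(...) {
  children <- list(...)
  if (length(children) < 2) validation_error("OR needs at least 2 children")
  stopifnot(all(vapply(children, inherits, logical(1), "nw_predicate")))
  structure(list(op = "or", children = children), class = "nw_predicate")
}

#' @rdname rule_match
#' @export
rule_not <- function(p) {
  stopifnot(inherits(p, "nw_predicate"))
  structure(list(op = "not", child = p), class = "nw_predicate")
}

#' Bundle ordered rules for one topic
#'
#' An article is positive for the topic iff it passes *all* rules (pure
#' conjunction); rule order matters only for reporting.
#'
#' @param topic_id Integer topic identifier (unique within a configuration).
#' @param topic_name Human-readable topic name.
#' @param rules List of `nw_predicate` (at least one).
#' @return An object of class `nw_ruleset`.
#' @export
topic_ruleset <- function(topic_id, topic_name, rules) {
  if (inherits(rules, "nw_predicate")) rules <- list(rules)
  if (length(rules) < 1) validation_error("a topic needs at least one rule")
  stopifnot(all(vapply(rules, inherits, logical(1), "nw_predicate")))
  structure(list(topic_id = as.integer(topic_id),
                 topic_name = as.character(topic_name),
                 rules = rules), class = "nw_ruleset")
}

# ---- config round-trip -----------------------------------------------------

predicate_to_list <- function(p) {
  switch(p$op,
    match = list(op = "match", scope = p$scope, keywords = as.list(p$keywords),
                 min_distinct = p$min_distinct),
    and = list(op = "and", children = lapply(p$children, predicate_to_list)),
    or = list(op = "or", children = lapply(p$children, predicate_to_list)),
    not = list(op = "not", child = predicate_to_list(p$child))
  )
}

predicate_from_list <- function(x, path = "rule") {
  op <- x$op
  if (is.null(op)) validation_error("%s: missing 'op'", path)
  if (op == "match") {
    scope <- x$scope
    if (is.null(scope) || !scope %in% c("title", "body", "sentence")) {
      validation_error("%s: unknown or missing scope '%s'", path,
                       scope %||% "<missing>")
    }
    rule_match(scope, unlist(x$keywords), x$min_distinct %||% 1L)
  } else if (op %in% c("and", "or")) {
    kids <- x$children
    if (is.null(kids) || length(kids) < 2) {
      validation_error("%s: '%s' needs >= 2 children", path, op)
    }
    parsed <- lapply(seq_along(kids), function(i) {
      predicate_from_list(kids[[i]], paste0(path, ".children[", i, "]"))
    })
    do.call(if (op == "and") rule_and else rule_or, parsed)
  } else if (op == "not") {
    if (is.null(x$child)) validation_error("%s: 'not' needs a child", path)
    rule_not(predicate_from_list(x$child, paste0(path, ".child")))
  } else {
    validation_error("%s: unknown op '%s'", path, op)
  }
}

#' Parse topic rule sets from a YAML or JSON config
#'
#' Schema: a list of topics, each `{topic_id, topic_name, rules: [...]}` where
#' a rule is `{op: match, scope, keywords, min_distinct}` or
#' `{op: and|or, children: [...]}` or `{op: not, child: {...}}`. Violations
#' are reported with the path into the config.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or an already-parsed
#'   list of the same shape.
#' @return A named list of `nw_ruleset`, names `topic_<id>`.
#' @seealso [write_ruleset()] for the inverse.
#' @export
parse_ruleset <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("rule config '%s' does not exist", config),
            class = "newswatch_io_error")
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.null(config$topics)) config <- config$topics
  out <- lapply(seq_along(config), function(i) {
    tp <- config[[i]]
    where <- sprintf("topics[%d]", i)
    if (is.null(tp$topic_id)) validation_error("%s: missing topic_id", where)
    rules <- lapply(seq_along(tp$rules), function(j) {
      predicate_from_list(tp$rules[[j]], sprintf("%s.rules[%d]", where, j))
    })
    topic_ruleset(tp$topic_id, tp$topic_name %||% paste("topic", tp$topic_id), rules)
  })
  ids <- vapply(out, function(r) r$topic_id, integer(1))
  if (anyDuplicated(ids)) {
    validation_error("duplicate topic_id %d in configuration", ids[duplicated(ids)][1])
  }
  setNames(out, paste0("topic_", ids))
}

#' Serialize rule sets to YAML or JSON
#'
#' @param rulesets List of `nw_ruleset` (as from [parse_ruleset()]).
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(rulesets, path) {
  payload <- list(topics = lapply(unname(rulesets), function(r) {
    list(topic_id = r$topic_id, topic_name = r$topic_name,
         rules = lapply(r$rules, predicate_to_list))
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

# ---- evaluation ------------------------------------------------------------

# tokenized view of one article, computed once and reused across predicates
article_context <- function(article, sentences) {
  list(
    title = tokenize1(article$title[[1]]),
    body = tokenize1(article$body[[1]]),
    sent = nw_tokenize(sentences$text)
  )
}

# TRUE iff the phrase's token sequence occurs contiguously in tokens
phrase_in_tokens <- function(phrase_tokens, tokens) {
  np <- length(phrase_tokens)
  nt <- length(tokens)
  if (np == 0 || nt < np) return(FALSE)
  if (np == 1) return(phrase_tokens %in% tokens)
  starts <- which(tokens == phrase_tokens[1])
  starts <- starts[starts + np - 1L <= nt]
  for (s in starts) {
    if (all(tokens[s:(s + np - 1L)] == phrase_tokens)) return(TRUE)
  }
  FALSE
}

# number of distinct phrases from `keywords` present in `tokens`
count_distinct_phrases <- function(keywords, tokens) {
  sum(vapply(nw_tokenize(keywords), phrase_in_tokens, logical(1), tokens = tokens))
}

eval_predicate_ctx <- function(p, ctx) {
  if (p$op == "match") {
    if (p$scope == "sentence") {
      hits <- which(vapply(ctx$sent, function(tk) {
        count_distinct_phrases(p$keywords, tk) >= p$min_distinct
      }, logical(1))) - 1L
      return(list(truth = length(hits) > 0, matched = hits))
    }
    tokens <- if (p$scope == "title") ctx$title else ctx$body
    return(list(truth = count_distinct_phrases(p$keywords, tokens) >= p$min_distinct,
                matched = integer(0)))
  }
  if (p$op == "not") {
    res <- eval_predicate_ctx(p$child, ctx)
    return(list(truth = !res$truth, matched = integer(0)))
  }
  results <- lapply(p$children, eval_predicate_ctx, ctx = ctx)
  truths <- vapply(results, `[[`, logical(1), "truth")
  truth <- if (p$op == "and") all(truths) else any(truths)
  matched <- if (truth) {
    contributing <- if (p$op == "and") results else results[truths]
    sort(unique(unlist(lapply(contributing, `[[`, "matched"))))
  } else {
    integer(0)
  }
  list(truth = truth, matched = as.integer(matched))
}

#' Evaluate one predicate against an article
#'
#' @param p An `nw_predicate`.
#' @param article One-row corpus tibble.
#' @param sentences Sentence index for the article ([segment_sentences()]).
#' @return A list with `truth` (logical) and `matched_sentences` (0-based
#'   indices of sentences that satisfied sentence-scope matches contributing
#'   to a true outcome).
#' @export
evaluate_predicate <- function(p, article, sentences) {
  res <- eval_predicate_ctx(p, article_context(article, sentences))
  list(truth = res$truth, matched_sentences = res$matched)
}

#' Evaluate a topic's full rule set against an article
#'
#' The article passes iff every rule passes; matched sentences are the union
#' over rules (these become the topic-focused summarization pseudolabels).
#'
#' @param article One-row corpus tibble.
#' @param sentences Sentence index for the article.
#' @param ruleset An `nw_ruleset`.
#' @return A list with `article_id`, `topic_id`, `passed`, `per_rule`
#'   (logical vector) and `matched_sentences` (0-based integer vector).
#' @export
evaluate_rules <- function(article, sentences, ruleset) {
  ctx <- article_context(article, sentences)
  results <- lapply(ruleset$rules, eval_predicate_ctx, ctx = ctx)
  per_rule <- vapply(results, `[[`, logical(1), "truth")
  list(
    article_id = article$article_id[[1]],
    topic_id = ruleset$topic_id,
    passed = all(per_rule),
    per_rule = per_rule,
    matched_sentences = sort(unique(unlist(lapply(results, `[[`, "matched"))))
  )
}

#' Apply rule sets to a whole corpus
#'
#' @param corpus A corpus tibble.
#' @param rulesets List of `nw_ruleset`.
#' @param sentences Optional precomputed sentence index ([segment_corpus()]);
#'   computed with the default splitter when omitted.
#' @return A long tibble with one row per (article, topic): `article_id`,
#'   `topic_id`, `passed`, `per_rule` (list-column), `matched_sentences`
#'   (list-column of 0-based indices). Summarize with [rule_report()].
#' @export
classify_corpus <- function(corpus, rulesets, sentences = NULL) {
  if (nrow(corpus) == 0) {
    out <- tibble::tibble(article_id = character(0), topic_id = integer(0),
                          passed = logical(0), per_rule = list(),
                          matched_sentences = list())
    attr(out, "n_articles") <- 0L
    return(out)
  }
  if (is.null(sentences)) sentences <- segment_corpus(corpus)
  sent_split <- split(sentences, factor(sentences$article_id, levels = corpus$article_id))
  empty_sent <- sentences[0, , drop = FALSE]
  rows <- purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    art <- corpus[i, , drop = FALSE]
    sn <- sent_split[[art$article_id]] %||% empty_sent
    ctx <- article_context(art, sn)
    purrr::map_dfr(rulesets, function(rs) {
      results <- lapply(rs$rules, eval_predicate_ctx, ctx = ctx)
      per_rule <- vapply(results, `[[`, logical(1), "truth")
      tibble::tibble(
        article_id = art$article_id,
        topic_id = rs$topic_id,
        passed = all(per_rule),
        per_rule = list(per_rule),
        matched_sentences = list(sort(unique(unlist(lapply(results, `[[`, "matched")))))
      )
    })
  })
  attr(rows, "n_articles") <- nrow(corpus)
  rows
}
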