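# Independent oracles, deliberately coded along different algorithmic routes
# than the package implementations they check.

# --- brute-force predicate evaluator ---------------------------------------
# Works on raw strings with regex counting instead of token-vector scanning.
bf_tokens <- function(text) {
  x <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  x[nzchar(x)]
}

bf_phrase_present <- function(phrase, text) {
  padded <- paste0(" ", paste(bf_tokens(text), collapse = " "), " ")
  grepl(paste0(" ", paste(bf_tokens(phrase), collapse = " "), " "), padded,
        fixed = TRUE)
}

bf_distinct_count <- function(keywords, text) {
  sum(vapply(keywords, bf_phrase_present, logical(1), text = text))
}

# returns list(truth, matched) like the package evaluator
bf_eval <- function(p, title, sentence_texts) {
  if (p$op == "match") {
    if (p$scope == "title") {
      return(list(truth = bf_distinct_count(p$keywords, title) >= p$min_distinct,
                  matched = integer(0)))
    }
    if (p$scope == "body") {
      body <- paste(sentence_texts, collapse = " ")
      return(list(truth = bf_distinct_count(p$keywords, body) >= p$min_distinct,
                  matched = integer(0)))
    }
    hits <- which(vapply(sentence_texts, function(s) {
      bf_distinct_count(p$keywords, s) >= p$min_distinct
    }, logical(1))) - 1L
    return(list(truth = length(hits) > 0, matched = as.integer(hits)))
  }
  if (p$op == "not") {
    r <- bf_eval(p$child, title, sentence_texts)
    return(list(truth = !r$truth, matched = integer(0)))
  }
  rs <- lapply(p$children, bf_eval, title = title, sentence_texts = sentence_texts)
  truths <- vapply(rs, `[[`, logical(1), "truth")
  truth <- if (p$op == "and") all(truths) else any(truths)
  matched <- if (truth) {
    use <- if (p$op == "and") rs else rs[truths]
    sort(unique(unlist(lapply(use, `[[`, "matched"))))
  } else integer(0)
  list(truth = truth, matched = as.integer(matched))
}

# random predicate tree over a token universe, depth <= max_depth
random_predicate <- function(universe, max_depth = 4L) {
  leaf <- function() {
    kws <- sample(universe, sample(1:3, 1))
    rule_match(sample(c("title", "body", "sentence"), 1), kws,
               min_distinct = sample.int(length(kws), 1))
  }
  build <- function(depth) {
    if (depth >= max_depth || runif(1) < 0.4) return(leaf())
    op <- sample(c("and", "or", "not"), 1)
    if (op == "not") return(rule_not(build(depth + 1L)))
    kids <- lapply(seq_len(sample(2:3, 1)), function(i) build(depth + 1L))
    do.call(if (op == "and") rule_and else rule_or, kids)
  }
  build(0L)
}

# random article made of simple sentences over the same universe
random_article <- function(universe, id = "a1", n_sent = sample(2:6, 1)) {
  sents <- vapply(seq_len(n_sent), function(i) {
    paste0(paste(sample(universe, sample(3:7, 1), replace = TRUE),
                 collapse = " "), ".")
  }, character(1))
  tibble::tibble(article_id = id,
                 title = paste(sample(universe, 3, replace = TRUE), collapse = " "),
                 body = paste(sents, collapse = " "),
                 source = "s", published_at = as.Date("2021-06-01"),
                 country_tags = list("US"), language = "en")
}

# --- independent ROUGE oracles ---------------------------------------------
# recursive memoized LCS (different route than the package's iterative DP)
bf_lcs <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0 || j == 0) return(0L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- if (a[i] == b[j]) f(i - 1L, j - 1L) + 1L else max(f(i - 1L, j), f(i, j - 1L))
    assign(key, v, envir = memo)
    v
  }
  f(length(a), length(b))
}

bf_rouge1_f1 <- function(cand, ref) {
  ct <- bf_tokens(cand); rt <- bf_tokens(ref)
  if (length(ct) == 0 || length(rt) == 0) return(0)
  ov <- 0
  rt_left <- rt
  for (tok in ct) {
    hit <- match(tok, rt_left)
    if (!is.na(hit)) { ov <- ov + 1; rt_left <- rt_left[-hit] }
  }
  p <- ov / length(ct); r <- ov / length(rt)
  if (p + r == 0) return(0)
  100 * 2 * p * r / (p + r)
}

# --- O(n^2) pairwise ROC-AUC oracle ----------------------------------------
bf_roc_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# brute-force average precision
bf_pr_auc <- function(score, label) {
  ord <- order(-score, seq_along(score))
  y <- label[ord]
  hits <- 0; s <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) { hits <- hits + 1; s <- s + hits / i }
  }
  s / sum(y)
}

# dictionary-based entity extractor injected in geo tests
make_dictionary_ner <- function(names) {
  function(text) {
    found <- names[vapply(names, function(nm) {
      grepl(nm, text, fixed = TRUE)
    }, logical(1))]
    pos <- vapply(found, function(nm) regexpr(nm, text, fixed = TRUE)[1], numeric(1))
    found[order(pos)]
  }
}
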