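test_that("sentence-scope matches report the matching sentences", {
  art <- tibble::tibble(article_id = "a", title = "Hospital news",
                        body = "Nurses met. The strike began.")
  s <- segment_sentences(art)
  res <- evaluate_predicate(rule_match("sentence", "strike"), art, s)
  expect_true(res$truth)
  expect_equal(res$matched_sentences, 1L)
  # negation yields truth without matched sentences
  res2 <- evaluate_predicate(rule_not(rule_match("title", "sports")), art, s)
  expect_true(res2$truth)
  expect_length(res2$matched_sentences, 0)
})

test_that("keyword matching respects token boundaries and distinct-phrase counting", {
  art <- tibble::tibble(article_id = "a", title = "The nursery opened",
                        body = "A nursery rhyme. Nurse Jones and the nurse spoke.")
  s <- segment_sentences(art)
  # "nurse" must not fire on "nursery"
  expect_false(evaluate_predicate(rule_match("title", "nurse"), art, s)$truth)
  # two occurrences of one phrase are one distinct phrase
  expect_false(evaluate_predicate(
    rule_match("sentence", c("nurse", "doctor"), min_distinct = 2), art, s)$truth)
  # multi-token phrase must be contiguous
  art2 <- tibble::tibble(article_id = "b", title = "t",
                         body = "Health care workers protested. Health of care teams.")
  s2 <- segment_sentences(art2)
  res <- evaluate_predicate(rule_match("sentence", "health care"), art2, s2)
  expect_equal(res$matched_sentences, 0L)
})

test_that("rule sets are pure conjunctions with per-rule reporting", {
  art <- tibble::tibble(article_id = "a", title = "Doctors strike",
                        body = "The walkout and strike grew. Sports update.")
  s <- segment_sentences(art)
  rs <- topic_ruleset(1, "strikes", list(
    rule_match("sentence", c("strike", "walkout"), min_distinct = 2),
    rule_not(rule_match("body", "celebrity"))
  ))
  res <- evaluate_rules(art, s, rs)
  expect_true(res$passed)
  expect_equal(res$per_rule, c(TRUE, TRUE))
  expect_equal(res$matched_sentences, 0L)
  rs2 <- topic_ruleset(1, "strikes", list(
    rule_match("sentence", c("strike", "walkout"), min_distinct = 2),
    rule_not(rule_match("body", "sports"))
  ))
  res2 <- evaluate_rules(art, s, rs2)
  expect_false(res2$passed)
  expect_equal(res2$per_rule, c(TRUE, FALSE))
})

test_that("random predicate trees agree with the brute-force evaluator", {
  set.seed(2024)
  universe <- c("strike", "nurse", "vaccine", "hospital", "funding", "burnout",
                "deaths", "training", "report", "city")
  n_cases <- 300
  for (i in seq_len(n_cases)) {
    p <- random_predicate(universe)
    art <- random_article(universe)
    s <- segment_sentences(art)
    got <- evaluate_predicate(p, art, s)
    want <- bf_eval(p, art$title, s$text)
    expect_identical(got$truth, want$truth)
    expect_identical(got$matched_sentences, want$matched)
  }
})

test_that("NOT-free rulesets are monotone under appending a matched keyword", {
  set.seed(99)
  universe <- c("strike", "nurse", "vaccine", "hospital", "funding")
  no_not <- function(p) {
    if (p$op == "match") return(TRUE)
    if (p$op == "not") return(FALSE)
    all(vapply(p$children, no_not, logical(1)))
  }
  checked <- 0
  while (checked < 50) {
    p <- random_predicate(universe, max_depth = 3)
    if (!no_not(p)) next
    art <- random_article(universe)
    s <- segment_sentences(art)
    if (!evaluate_predicate(p, art, s)$truth) { checked <- checked + 1; next }
    art2 <- art
    art2$body <- paste(art$body, "The strike nurse vaccine hospital funding grew.")
    s2 <- segment_sentences(art2)
    expect_true(evaluate_predicate(p, art2, s2)$truth)
    checked <- checked + 1
  }
})

test_that("rule configs round-trip through serialize and parse", {
  set.seed(7)
  universe <- c("alpha", "beta", "gamma", "delta")
  for (fmt in c(".yaml", ".json")) {
    rules <- setNames(lapply(1:3, function(t) {
      topic_ruleset(t, paste("topic", t),
                    lapply(1:2, function(j) random_predicate(universe, 3)))
    }), paste0("topic_", 1:3))
    f <- withr::local_tempfile(fileext = fmt)
    write_ruleset(rules, f)
    back <- parse_ruleset(f)
    expect_equal(lapply(back, unclass), lapply(rules, unclass))
  }
})

test_that("malformed rule configs are rejected with a path into the config", {
  bad <- list(list(topic_id = 1, topic_name = "x",
                   rules = list(list(op = "match", scope = "paragraph",
                                     keywords = list("a")))))
  expect_error(parse_ruleset(bad), "topics\\[1\\].rules\\[1\\].*scope",
               class = "newswatch_validation_error")
  expect_error(rule_match("title", c("a", "b"), min_distinct = 3),
               "min_distinct", class = "newswatch_validation_error")
  expect_error(rule_match("title", c("a", "a")), "duplicate",
               class = "newswatch_validation_error")
  expect_error(rule_and(rule_match("title", "a")), "2 children",
               class = "newswatch_validation_error")
})

test_that("the packaged default rule file parses to the built-in rule sets", {
  f <- system.file("extdata", "rules", "default_rules.yaml", package = "newswatch")
  expect_true(nzchar(f))
  expect_equal(lapply(parse_ruleset(f), unclass),
               lapply(default_rulesets(), unclass))
})

test_that("corpus classification reproduces planted counts and a coherent report", {
  gen <- generate_corpus(synthetic_config(n_articles = 400, prevalence = 0.02,
                                          duplicate_frac = 0, seed = 301))
  s <- segment_corpus(gen$corpus)
  labs <- classify_corpus(gen$corpus, default_rulesets(), s)
  planted <- purrr::map_dfr(seq_len(nrow(gen$truth)), function(i) {
    tibble::tibble(article_id = gen$truth$article_id[i],
                   topic_id = gen$truth$topics[[i]])
  })
  pos <- labs[labs$passed, ]
  expect_setequal(paste(pos$article_id, pos$topic_id),
                  paste(planted$article_id, planted$topic_id))
  rep <- rule_report(labs)
  expect_equal(sum(rep$topics$n_positive), nrow(planted))
  expect_equal(rep$topics$rate_pct, 100 * rep$topics$n_positive / nrow(gen$corpus))
  # overlap: symmetric, NA diagonal, bounded by the smaller topic count
  ov <- rep$overlap
  expect_true(all(is.na(diag(ov))))
  expect_identical(ov, t(ov))
  for (a in 1:5) for (b in (a + 1):6) {
    expect_lte(ov[a, b], min(rep$topics$n_positive[c(a, b)]))
  }
  # brute-force recount of one overlap cell
  ids1 <- pos$article_id[pos$topic_id == 1]
  ids2 <- pos$article_id[pos$topic_id == 2]
  expect_equal(ov[1, 2], length(intersect(ids1, ids2)))
})

test_that("a corpus with no matches yields an all-zero report", {
  corpus <- tibble::tibble(article_id = "a", title = "quiet day",
                           body = "Nothing happened in the town today.",
                           source = "s", published_at = as.Date("2021-01-01"),
                           country_tags = list("US"), language = "en")
  labs <- classify_corpus(corpus, default_rulesets())
  expect_false(any(labs$passed))
  expect_equal(sum(rule_report(labs)$topics$n_positive), 0L)
})
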