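test_that("greedy oracle self-matches identical highlights", {
  src <- c("nurses went on strike", "the weather was mild", "officials met today")
  expect_equal(greedy_oracle_labels(src, src[c(1, 3)]), c(0L, 2L))
  # one highlight sharing 3 tokens picks the overlapping source
  src2 <- c("alpha beta gamma delta", "epsilon zeta eta theta")
  expect_equal(greedy_oracle_labels(src2, "alpha beta gamma"), 0L)
  expect_error(greedy_oracle_labels(character(0), "x"),
               class = "newswatch_validation_error")
})

test_that("greedy selection equals exhaustive per-step argmax on small instances", {
  set.seed(31)
  vocab <- c("strike", "nurse", "vaccine", "city", "report", "update",
             "mortality", "stress")
  for (i in 1:60) {
    n_src <- sample(2:8, 1)
    src <- vapply(seq_len(n_src), function(j) {
      paste(sample(vocab, sample(3:6, 1), replace = TRUE), collapse = " ")
    }, character(1))
    hls <- vapply(seq_len(sample(1:3, 1)), function(j) {
      paste(sample(vocab, sample(2:5, 1), replace = TRUE), collapse = " ")
    }, character(1))
    got <- greedy_oracle_labels(src, hls)
    # independent exhaustive per-step search using the oracle ROUGE-1
    sel <- integer(0)
    for (h in hls) {
      avail <- setdiff(seq_len(n_src), sel)
      sc <- vapply(avail, function(k) bf_rouge1_f1(src[k], h), numeric(1))
      sel <- c(sel, avail[which.max(sc)])
    }
    expect_identical(got, sort(sel) - 1L)
  }
})

test_that("training labels merge rule and human sources and validate indices", {
  gen <- generate_corpus(synthetic_config(n_articles = 40, prevalence = 0.2,
                                          duplicate_frac = 0, seed = 601))
  s <- segment_corpus(gen$corpus)
  labs <- classify_corpus(gen$corpus, default_rulesets(), s)
  pos_id <- labs$article_id[labs$passed][1]
  ann <- tibble::tibble(article_id = pos_id, selected_indices = list(c(0L, 1L)))
  out <- build_training_labels(labs, ann, s)
  i <- match(pos_id, out$article_id)
  expect_equal(out$global_indices[[i]], c(0L, 1L))
  expect_true(length(out$topic_indices[[i]]) > 0)
  # rule-only articles carry no global labels
  other <- setdiff(out$article_id, pos_id)
  expect_true(all(vapply(other, function(id) {
    is.null(out$global_indices[[match(id, out$article_id)]])
  }, logical(1))))
  # over-long and out-of-range human selections are rejected
  expect_error(build_training_labels(labs,
    tibble::tibble(article_id = pos_id, selected_indices = list(0:3)), s),
    "1-3", class = "newswatch_validation_error")
  expect_error(build_training_labels(labs,
    tibble::tibble(article_id = pos_id, selected_indices = list(999L)), s),
    "out of range", class = "newswatch_validation_error")
})

test_that("an absent label source contributes exactly zero gradient", {
  set.seed(41)
  d <- 6; h <- 4
  params <- newswatch:::mlp_init(d, h, 2L, seed = 1)
  X <- matrix(rnorm(5 * d), 5, d)
  Y <- cbind(global = c(1, 0, 1, 0, 0), topic = 0)
  M <- cbind(rep(1, 5), rep(0, 5))  # topic head masked out entirely
  g <- newswatch:::mlp_grads(params, X, Y, M)
  # analytic gradient of the topic output column is identically zero
  expect_true(all(g$W2[, 2] == 0))
  expect_equal(unname(g$b2[2]), 0)
  # finite-difference check on one masked and one unmasked parameter
  loss_at <- function(p) {
    fw <- newswatch:::mlp_forward(p, X)
    newswatch:::bce_loss_masked(fw$P, Y, M)
  }
  eps <- 1e-6
  p_up <- params; p_up$W2[1, 2] <- p_up$W2[1, 2] + eps
  expect_equal((loss_at(p_up) - loss_at(params)) / eps, 0)
  p_up2 <- params; p_up2$W2[1, 1] <- p_up2$W2[1, 1] + eps
  fd <- (loss_at(p_up2) - loss_at(params)) / eps
  expect_equal(unname(fd), unname(g$W2[1, 1]), tolerance = 1e-4)
})

test_that("summaries rank by summed head scores with document-order output", {
  # fixed scores: sums 1.7, 0.2, 1.6, 0.3 select sentences 0 and 2 (k=3 -> +3)
  sc <- c(0.9 + 0.8, 0.1 + 0.1, 0.7 + 0.9, 0.2 + 0.1)
  sel <- newswatch:::select_top_k(sc, 3)
  expect_equal(sort(sel), c(1, 3, 4))
  # uniform scores: positional tie-break
  expect_equal(newswatch:::select_top_k(rep(0.5, 5), 3), 1:3)
})

test_that("summarize_article emits verbatim sentences, at most min(3, n)", {
  gen <- generate_corpus(synthetic_config(n_articles = 30, prevalence = 0.3,
                                          duplicate_frac = 0, seed = 602))
  s <- segment_corpus(gen$corpus)
  labs <- classify_corpus(gen$corpus, default_rulesets(), s)
  lab <- build_training_labels(labs, NULL, s)
  m <- train_summarizer(gen$corpus, s, lab,
                        encoder = hashing_encoder(dim = 128, seed = 4),
                        config = summarizer_config(epochs = 1, learning_rate = 1e-3,
                                                   hidden = 8, seed = 2))
  for (i in seq_len(nrow(gen$corpus))) {
    art <- gen$corpus[i, ]
    out <- summarize_article(m, art, s)
    n_sent <- sum(s$article_id == art$article_id)
    expect_equal(nrow(out), min(3L, n_sent))
    expect_true(all(out$text %in% s$text[s$article_id == art$article_id]))
    expect_false(is.unsorted(out$sentence))
  }
  # 2-sentence article yields both sentences
  short <- tibble::tibble(article_id = "s1", title = "t",
                          body = "One here. Two here.", source = "s",
                          published_at = as.Date("2021-01-01"),
                          country_tags = list("US"), language = "en")
  ss <- segment_corpus(short)
  expect_equal(nrow(summarize_article(m, short, ss)), 2L)
  # empty article: empty summary
  empty <- dplyr::mutate(short, article_id = "s2", body = "")
  expect_equal(nrow(summarize_article(m, empty, segment_corpus(empty))), 0L)
})

test_that("the dual-head scorer recovers planted key sentences on held-out articles", {
  gen <- generate_corpus(synthetic_config(n_articles = 300, prevalence = 0.25,
                                          duplicate_frac = 0, seed = 603))
  s <- segment_corpus(gen$corpus)
  labs <- classify_corpus(gen$corpus, default_rulesets(), s)
  lab <- build_training_labels(labs, NULL, s)
  held <- with(list(), {set.seed(9); sample(lab$article_id, 60)})
  m <- train_summarizer(gen$corpus, s, lab[!lab$article_id %in% held, ],
                        encoder = hashing_encoder(dim = 512, seed = 3),
                        config = summarizer_config(epochs = 4, learning_rate = 1e-2,
                                                   hidden = 16, seed = 7))
  hits <- vapply(held, function(id) {
    sn <- s[s$article_id == id, ]
    scd <- score_sentences(m, sn)
    top1 <- scd$sentence[which.max(scd$p_global + scd$p_topic)]
    keys <- sort(unique(unlist(gen$truth$key_sentences[[match(id, gen$truth$article_id)]])))
    top1 %in% keys
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("training without any labels errors; zero epochs returns initialization", {
  gen <- generate_corpus(synthetic_config(n_articles = 10, prevalence = 0.5,
                                          duplicate_frac = 0, seed = 604))
  s <- segment_corpus(gen$corpus)
  labs <- classify_corpus(gen$corpus, default_rulesets(), s)
  lab <- build_training_labels(labs, NULL, s)
  empty <- lab[0, ]
  expect_error(train_summarizer(gen$corpus, s, empty),
               class = "newswatch_training_error")
  enc <- hashing_encoder(dim = 32, seed = 1)
  m0 <- train_summarizer(gen$corpus, s, lab, encoder = enc,
                         config = summarizer_config(epochs = 0, hidden = 8, seed = 3))
  init <- newswatch:::mlp_init(32, 8, 2L,
                               seed = newswatch:::derive_seed(3L, "sum_init"))
  expect_identical(m0$params, init)
})

test_that("summary evaluation reports per-article and mean ROUGE on the x100 scale", {
  preds <- tibble::tibble(article_id = c("a", "b"),
                          summary = c("nurses strike today", "alpha beta"),
                          topic_id = c(1L, 2L))
  refs <- tibble::tibble(article_id = c("a", "b"),
                         summary = c("nurses strike today", "gamma delta"))
  ev <- evaluate_summaries(preds, refs)
  expect_equal(ev$per_article$mean_rouge[1], 100)
  expect_equal(ev$per_article$mean_rouge[2], 0)
  expect_equal(ev$overall$mean_rouge, 50)
  expect_equal(nrow(ev$by_topic), 2L)
  expect_warning(
    evaluate_summaries(preds, dplyr::mutate(refs, summary = c("x", ""))),
    "empty reference")
})
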