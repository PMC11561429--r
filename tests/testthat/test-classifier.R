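make_labelled_corpus <- function(n, prevalence, seed) {
  gen <- generate_corpus(synthetic_config(n_articles = n, prevalence = prevalence,
                                          duplicate_frac = 0, seed = seed))
  s <- segment_corpus(gen$corpus)
  labs <- classify_corpus(gen$corpus, default_rulesets(), s)
  list(gen = gen, sentences = s, labels = labs,
       store = labels_from_rules(labs))
}

test_that("dataset splits keep all positives and cap the negatives", {
  x <- make_labelled_corpus(550, 0.05, 501)
  ds <- build_datasets(x$gen$corpus, x$store, split_spec(negative_cap = 100, seed = 3))
  n <- nrow(x$gen$corpus)
  expect_equal(nrow(ds$val$corpus), n - round(0.9 * n))
  n_pos_train <- sum(rowSums(ds$train$y) > 0)
  expect_equal(nrow(ds$train$corpus), n_pos_train + 100L)
  # every positive landing in the train split is retained
  Y <- newswatch:::label_matrix(x$gen$corpus, x$store)
  pos_ids <- rownames(Y)[rowSums(Y) > 0]
  val_ids <- ds$val$corpus$article_id
  expect_setequal(ds$train$corpus$article_id[rowSums(ds$train$y) > 0],
                  setdiff(pos_ids, val_ids))
  # negatives capped at 100
  expect_lte(sum(rowSums(ds$train$y) == 0), 100)
  # with a generous cap, all split negatives are retained
  ds2 <- build_datasets(x$gen$corpus, x$store, split_spec(negative_cap = 10^6, seed = 3))
  expect_equal(nrow(ds2$train$corpus), round(0.9 * n))
  # reproducible from the seed
  ds3 <- build_datasets(x$gen$corpus, x$store, split_spec(negative_cap = 100, seed = 3))
  expect_identical(ds$train$corpus$article_id, ds3$train$corpus$article_id)
  expect_error(build_datasets(x$gen$corpus,
                              dplyr::mutate(x$store, label = "negative"),
                              split_spec()),
               class = "newswatch_training_error")
})

test_that("an untrained zero head outputs probability 0.5 everywhere", {
  enc <- hashing_encoder(dim = 32, seed = 1)
  params <- newswatch:::mlp_init(32, 8, 6, init = "zero")
  clf <- structure(list(params = params, encoder = enc, topic_ids = 1:6),
                   class = "nw_classifier")
  gen <- generate_corpus(synthetic_config(n_articles = 5, seed = 1))
  P <- predict(clf, gen$corpus, type = "matrix")
  expect_true(all(P == 0.5))
  expect_true(all(P > 0 & P < 1))
})

test_that("prediction is batch-invariant and deterministic", {
  x <- make_labelled_corpus(80, 0.05, 502)
  enc <- hashing_encoder(dim = 64, seed = 2)
  ds <- build_datasets(x$gen$corpus, x$store, split_spec(seed = 1))
  clf <- suppressWarnings(train_classifier(
    ds$train, ds$val, enc,
    classifier_config(epochs = 1, eval_every = 50, hidden = 16,
                      learning_rate = 1e-3, seed = 4)))
  whole <- predict(clf, x$gen$corpus, type = "matrix")
  per_item <- do.call(rbind, lapply(seq_len(nrow(x$gen$corpus)), function(i) {
    predict(clf, x$gen$corpus[i, ], type = "matrix")
  }))
  expect_equal(unname(whole), unname(per_item), tolerance = 1e-12)
  expect_identical(whole, predict(clf, x$gen$corpus, type = "matrix"))
})

test_that("training is reproducible from its seed", {
  x <- make_labelled_corpus(60, 0.08, 503)
  enc <- hashing_encoder(dim = 32, seed = 2)
  ds <- build_datasets(x$gen$corpus, x$store, split_spec(seed = 1))
  cfg <- classifier_config(epochs = 2, eval_every = 25, hidden = 8,
                           learning_rate = 1e-3, seed = 11)
  c1 <- suppressWarnings(train_classifier(ds$train, ds$val, enc, cfg))
  c2 <- suppressWarnings(train_classifier(ds$train, ds$val, enc, cfg))
  expect_identical(c1$params, c2$params)
  expect_identical(c1$history, c2$history)
})

test_that("zero-epoch training leaves the model at initialization with empty history", {
  x <- make_labelled_corpus(30, 0.1, 504)
  enc <- hashing_encoder(dim = 32, seed = 2)
  ds <- build_datasets(x$gen$corpus, x$store, split_spec(seed = 1))
  cfg <- classifier_config(epochs = 0, eval_every = 10, hidden = 8, seed = 5)
  clf <- suppressWarnings(train_classifier(ds$train, ds$val, enc, cfg))
  init <- newswatch:::mlp_init(32, 8, ncol(ds$train$y),
                               seed = newswatch:::derive_seed(5L, "init"))
  expect_identical(clf$params, init)
  expect_equal(nrow(clf$history), 0L)
})

test_that("the learning-rate schedule peaks at the warmup boundary and ends at zero", {
  total <- 200; base <- 1e-3; frac <- 0.05
  w <- ceiling(frac * total)
  lrs <- vapply(1:total, lr_schedule, numeric(1),
                total_steps = total, base_lr = base, warmup_frac = frac)
  expect_equal(which.max(lrs), w)
  expect_equal(lrs[w], base)
  expect_equal(lrs[total], 0)
  # strictly increasing through warmup, strictly decreasing after
  expect_true(all(diff(lrs[1:w]) > 0))
  expect_true(all(diff(lrs[w:total]) < 0))
})

test_that("a tiny encoder recovers planted topics to high validation AUC", {
  # desk-scale parameter-recovery analogue of large-scale AUC reporting
  x <- make_labelled_corpus(400, 0.1, 505)
  enc <- hashing_encoder(dim = 512, seed = 3)
  ds <- build_datasets(x$gen$corpus, x$store, split_spec(seed = 2))
  cfg <- classifier_config(epochs = 10, eval_every = 400, hidden = 64,
                           learning_rate = 2e-2, seed = 6)
  clf <- suppressWarnings(train_classifier(ds$train, ds$val, enc, cfg))
  expect_gte(clf$val_auc, 0.95)
  expect_s3_class(tidy(clf), "tbl_df")
  expect_equal(glance(clf)$val_macro_auc, clf$val_auc)
})

test_that("single-class validation topics are skipped with a warning", {
  x <- make_labelled_corpus(60, c(0.3, 0, 0, 0, 0, 0), 506)
  enc <- hashing_encoder(dim = 32, seed = 2)
  ds <- build_datasets(x$gen$corpus, x$store, split_spec(seed = 1))
  expect_warning(
    train_classifier(ds$train, ds$val, enc,
                     classifier_config(epochs = 1, eval_every = 20, hidden = 8,
                                       learning_rate = 1e-3, seed = 1)),
    "single-class")
})

test_that("enrichment candidates are the top-scored rule negatives in order", {
  scores <- tibble::tibble(
    article_id = sprintf("a%02d", 1:10),
    topic_id = 1L,
    prob = c(0.1, 0.95, 0.4, 0.9, 0.2, 0.8, 0.3, 0.5, 0.6, 0.7)
  )
  labels <- tibble::tibble(article_id = sprintf("a%02d", 1:10), topic_id = 1L,
                           label = c("negative", "positive", rep("negative", 8)),
                           provenance = "rule")
  out <- select_enrichment_candidates(scores, labels, k = 3)
  expect_equal(out$article_id, c("a04", "a06", "a10"))  # a02 is rule-positive
  expect_equal(out$rank, 1:3)
  # ties broken by stable article order
  scores$prob <- 0.5
  tied <- select_enrichment_candidates(scores, labels, k = 3)
  expect_equal(tied$article_id, c("a01", "a03", "a04"))
  expect_equal(nrow(select_enrichment_candidates(scores, labels, k = 0)), 0L)
  expect_warning(select_enrichment_candidates(scores, labels, k = 50),
                 "only 9")
})

test_that("review verdicts re-enter the label store with enrichment provenance", {
  labels <- tibble::tibble(article_id = c("a", "b"), topic_id = 1L,
                           label = c("negative", "positive"), provenance = "rule")
  review <- tibble::tibble(article_id = c("a", "b"), topic_id = 1L,
                           verdict = c("positive", "positive"))
  out <- apply_review_verdicts(labels, review)
  expect_equal(out$label, c("positive", "positive"))
  expect_equal(out$provenance, c("human_enriched", "human_confirmed"))
  expect_error(apply_review_verdicts(labels,
                                     tibble::tibble(article_id = "zz", topic_id = 1L,
                                                    verdict = "positive")),
               class = "newswatch_validation_error")
})

test_that("the inference filter keeps the union of threshold and rank band", {
  scores <- tibble::tibble(article_id = c("a", "b", "c", "d"), topic_id = 1L,
                           prob = c(0.99, 0.96, 0.70, 0.20))
  kept <- apply_inference_filter(scores, c("1" = 1), threshold = 0.95,
                                 multiplier = 3)
  expect_setequal(kept$article_id, c("a", "b", "c"))
  expect_true(all(kept$above_threshold == c(TRUE, TRUE, FALSE)))
  # N = 0 and nothing above threshold: empty
  low <- dplyr::mutate(scores, prob = prob / 10)
  expect_equal(nrow(apply_inference_filter(low, c("1" = 0))), 0L)
  # all above threshold are kept regardless of N
  high <- dplyr::mutate(scores, prob = 0.99)
  expect_equal(nrow(apply_inference_filter(high, c("1" = 0))), 4L)
  # monotone in threshold: lowering it never shrinks the kept set
  k1 <- apply_inference_filter(scores, c("1" = 1), threshold = 0.95)
  k2 <- apply_inference_filter(scores, c("1" = 1), threshold = 0.5)
  expect_true(all(k1$article_id %in% k2$article_id))
})
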