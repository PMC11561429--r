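#' Training configuration for the topic classifier
#'
#' Defaults follow the published training schedule of the system this
#' package reimplements: 5 epochs, Adam at learning rate 1e-5, batch size 4,
#' linear warmup over the first 5% of steps then linear decay to 0,
#' evaluation every 5000 optimization steps, early stopping (checkpoint on
#' improvement) on validation macro ROC-AUC.
#'
#' @param epochs Number of passes over the training set.
#' @param learning_rate Peak Adam learning rate.
#' @param batch_size Minibatch size.
#' @param warmup_frac Fraction of steps for linear LR warmup, in (0, 1).
#' @param eval_every Evaluate on validation every this many steps (the end of
#'   training always evaluates).
#' @param hidden Hidden width of the classification head (affine -> ReLU ->
#'   affine -> sigmoid).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A list of class `nw_train_config`.
#' @export
classifier_config <- function(epochs = 5L, learning_rate = 1e-5, batch_size = 4L,
                              warmup_frac = 0.05, eval_every = 5000L,
                              hidden = 768L, seed = 1L) {
  stopifnot(epochs >= 0, learning_rate > 0, batch_size >= 1,
            warmup_frac > 0, warmup_frac < 1, eval_every >= 1, hidden >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), warmup_frac = warmup_frac,
                 eval_every = as.integer(eval_every), hidden = as.integer(hidden),
                 seed = as.integer(seed)), class = "nw_train_config")
}

#' Train/validation split specification
#'
#' 90/10 random article split; the training side keeps every positive and at
#' most `negative_cap` randomly subsampled negatives, while the validation
#' side is left unrebalanced.
#'
#' @param train_frac,val_frac Split fractions (must sum to 1).
#' @param negative_cap Maximum number of negatives retained in training
#'   (default 100,000).
#' @param seed Integer seed making the split reproducible.
#' @return A list of class `nw_split_spec`.
#' @export
split_spec <- function(train_frac = 0.9, val_frac = 0.1,
                       negative_cap = 100000L, seed = 1L) {
  if (abs(train_frac + val_frac - 1) > 1e-9) {
    validation_error("train_frac + val_frac must equal 1")
  }
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 negative_cap = as.integer(negative_cap),
                 seed = as.integer(seed)), class = "nw_split_spec")
}

#' Build a label store from rule-based classification
#'
#' @param rule_labels Tibble from [classify_corpus()].
#' @return A label-store tibble: `article_id`, `topic_id`, `label`
#'   (`"positive"`/`"negative"`), `provenance` (`"rule"`).
#' @export
labels_from_rules <- function(rule_labels) {
  tibble::tibble(
    article_id = rule_labels$article_id,
    topic_id = rule_labels$topic_id,
    label = ifelse(rule_labels$passed, "positive", "negative"),
    provenance = "rule"
  )
}

#' Fold human review verdicts back into a label store
#'
#' Applies verdicts from an enrichment-review file (see
#' [select_enrichment_candidates()]): each reviewed (article, topic) pair is
#' relabelled with provenance `"human_enriched"`; rule positives confirmed by
#' review get provenance `"human_confirmed"`.
#'
#' @param labels Label-store tibble.
#' @param review Tibble with `article_id`, `topic_id`, `verdict`
#'   (`"positive"`/`"negative"`).
#' @return The updated label store.
#' @export
apply_review_verdicts <- function(labels, review) {
  stopifnot(all(c("article_id", "topic_id", "verdict") %in% names(review)))
  bad <- setdiff(review$verdict, c("positive", "negative"))
  if (length(bad) > 0) validation_error("unknown verdict '%s'", bad[1])
  for (i in seq_len(nrow(review))) {
    hit <- labels$article_id == review$article_id[i] &
      labels$topic_id == review$topic_id[i]
    if (!any(hit)) {
      validation_error("review names unknown pair (%s, topic %s)",
                       review$article_id[i], review$topic_id[i])
    }
    was_positive <- labels$label[hit] == "positive"
    labels$label[hit] <- review$verdict[i]
    labels$provenance[hit] <- if (was_positive && review$verdict[i] == "positive")
      "human_confirmed" else "human_enriched"
  }
  labels
}

# label store -> 0/1 matrix, rows in corpus order, cols in sorted topic order
label_matrix <- function(corpus, labels) {
  topic_ids <- sort(unique(labels$topic_id))
  Y <- matrix(0, nrow(corpus), length(topic_ids),
              dimnames = list(corpus$article_id, paste0("topic_", topic_ids)))
  pos <- labels[labels$label == "positive", , drop = FALSE]
  for (t in seq_along(topic_ids)) {
    ids <- pos$article_id[pos$topic_id == topic_ids[t]]
    Y[corpus$article_id %in% ids, t] <- 1
  }
  attr(Y, "topic_ids") <- topic_ids
  Y
}

#' Split a labelled corpus into training and validation sets
#'
#' Random article-level split (reproducible from the spec's seed). Training
#' keeps all multilabel positives and at most `negative_cap` sampled
#' negatives; the validation set is left exactly as split (no rebalancing).
#'
#' @param corpus A corpus tibble.
#' @param labels Label-store tibble covering the corpus.
#' @param split An [split_spec()].
#' @return A list with `train` and `val`, each a list of `corpus` and `y`
#'   (0/1 article-by-topic matrix), plus `topic_ids`.
#' @export
build_datasets <- function(corpus, labels, split = split_spec()) {
  Y <- label_matrix(corpus, labels)
  topic_ids <- attr(Y, "topic_ids")
  if (sum(Y) == 0) {
    abort("no positive labels: classifier is untrainable",
          class = "newswatch_training_error")
  }
  n <- nrow(corpus)
  idx_train <- with_seed(derive_seed(split$seed, "split"), {
    sample.int(n, size = round(split$train_frac * n))
  })
  idx_val <- setdiff(seq_len(n), idx_train)
  is_pos <- rowSums(Y) > 0
  tr_pos <- intersect(idx_train, which(is_pos))
  tr_neg <- intersect(idx_train, which(!is_pos))
  if (length(tr_neg) > split$negative_cap) {
    tr_neg <- with_seed(derive_seed(split$seed, "negcap"), {
      sort(sample(tr_neg, split$negative_cap))
    })
  }
  keep <- sort(c(tr_pos, tr_neg))
  list(
    train = list(corpus = corpus[keep, , drop = FALSE],
                 y = Y[keep, , drop = FALSE]),
    val = list(corpus = corpus[idx_val, , drop = FALSE],
               y = Y[idx_val, , drop = FALSE]),
    topic_ids = topic_ids
  )
}

# macro-average ROC-AUC over topics; single-class topics are excluded with a
# warning and recorded in the "skipped" attribute
macro_roc_auc <- function(P, Y) {
  aucs <- rep(NA_real_, ncol(Y))
  for (t in seq_len(ncol(Y))) {
    if (length(unique(Y[, t])) < 2) next
    aucs[t] <- roc_auc(P[, t], Y[, t])
  }
  skipped <- which(is.na(aucs))
  if (length(skipped) == ncol(Y)) return(structure(NA_real_, skipped = skipped))
  structure(mean(aucs, na.rm = TRUE), skipped = skipped, per_topic = aucs)
}

#' Train the multilabel topic classifier
#'
#' Encodes each article (title + body, 512-token cap) with the supplied
#' deterministic encoder and trains the classification head — affine to a
#' hidden layer, ReLU, affine to one logit per topic, sigmoid — with masked
#' multilabel binary cross-entropy, the Adam optimizer and a linear
#' warmup/decay schedule. A checkpoint is kept whenever the validation macro
#' ROC-AUC improves; the returned model carries the best checkpoint. Topics
#' with a single class in validation are excluded from the macro average
#' with a warning.
#'
#' @param train,val Lists with `corpus` and `y` as from [build_datasets()].
#' @param encoder Deterministic document encoder (default
#'   [hashing_encoder()]).
#' @param config A [classifier_config()].
#' @return An object of class `nw_classifier`.
#' @export
train_classifier <- function(train, val, encoder = hashing_encoder(),
                             config = classifier_config()) {
  stopifnot(nrow(train$corpus) >= 1)
  Xtr <- encode_corpus(encoder, train$corpus)
  Ytr <- train$y
  n_topics <- ncol(Ytr)
  params <- mlp_init(encoder_dim(encoder), config$hidden, n_topics,
                     seed = derive_seed(config$seed, "init"))
  have_val <- !is.null(val) && nrow(val$corpus) > 0
  Xval <- if (have_val) encode_corpus(encoder, val$corpus) else NULL
  warned <- FALSE
  eval_fn <- if (have_val) {
    function(p) {
      auc <- macro_roc_auc(mlp_forward(p, Xval)$P, val$y)
      sk <- attr(auc, "skipped")
      if (length(sk) > 0 && !warned) {
        warned <<- TRUE
        warn(sprintf("validation AUC skips single-class topic(s): %s",
                     paste(colnames(val$y)[sk], collapse = ", ")))
      }
      as.numeric(auc)
    }
  } else {
    NULL
  }
  fit <- train_mlp_loop(params, Xtr, Ytr,
                        mask = matrix(1, nrow(Xtr), n_topics),
                        config = config, eval_fn = eval_fn)
  val_auc <- if (have_val) eval_fn(fit$best_params) else NA_real_
  structure(list(
    params = fit$best_params,
    encoder = encoder,
    config = config,
    topic_ids = attr(train$y, "topic_ids") %||%
      as.integer(sub("^topic_", "", colnames(Ytr))),
    history = fit$history,
    val_auc = val_auc,
    n_train = nrow(train$corpus)
  ), class = "nw_classifier")
}

#' Predict topic probabilities for articles
#'
#' Deterministic forward pass of the trained head over encoded articles.
#' Topic probabilities are independent (no normalization across topics) and
#' strictly inside (0, 1).
#'
#' @param object An `nw_classifier`.
#' @param corpus A corpus tibble.
#' @param type `"tibble"` (default) for a long tibble `article_id`,
#'   `topic_id`, `prob`; `"matrix"` for an article-by-topic matrix.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.nw_classifier <- function(object, corpus, type = c("tibble", "matrix"), ...) {
  type <- match.arg(type)
  X <- encode_corpus(object$encoder, corpus)
  P <- mlp_forward(object$params, X)$P
  dimnames(P) <- list(corpus$article_id, paste0("topic_", object$topic_ids))
  if (type == "matrix") return(P)
  tibble::tibble(
    article_id = rep(corpus$article_id, times = length(object$topic_ids)),
    topic_id = rep(object$topic_ids, each = nrow(corpus)),
    prob = as.vector(P)
  )
}

#' @describeIn train_classifier `tidy()` returns the training history
#'   (step, epoch, learning rate, loss, validation macro ROC-AUC).
#' @param x An `nw_classifier`.
#' @param ... Unused.
#' @export
tidy.nw_classifier <- function(x, ...) x$history

#' @describeIn train_classifier `glance()` returns a one-row model summary.
#' @export
glance.nw_classifier <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_topics = length(x$topic_ids),
    hidden = x$config$hidden,
    epochs = x$config$epochs,
    steps = if (nrow(x$history) > 0) max(x$history$step) else 0L,
    val_macro_auc = x$val_auc
  )
}

#' @describeIn train_classifier `autoplot()` draws loss and validation AUC
#'   against training step.
#' @param object An `nw_classifier`.
#' @export
autoplot.nw_classifier <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "val_metric"),
                           names_to = "series", values_to = "value")
  h <- h[!is.na(h$value), , drop = FALSE]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "Optimization step", y = NULL,
                  title = "Classifier training history") +
    ggplot2::theme_minimal()
}

#' Rank rule-negative articles for human enrichment review
#'
#' Per topic, the `k` rule-negative articles with the highest predicted
#' probability, descending (ties broken by stable article order). These go
#' to human review; verdicts re-enter the label store via
#' [apply_review_verdicts()], converting false negatives into positives
#' before retraining.
#'
#' @param scores Long tibble `article_id`, `topic_id`, `prob` (from
#'   [predict.nw_classifier()]).
#' @param labels Label-store tibble.
#' @param k Number of candidates per topic (default 500).
#' @return A tibble `topic_id`, `rank`, `article_id`, `prob`.
#' @export
select_enrichment_candidates <- function(scores, labels, k = 500L) {
  k <- as.integer(k)
  stopifnot(k >= 0)
  if (k == 0L) {
    return(tibble::tibble(topic_id = integer(0), rank = integer(0),
                          article_id = character(0), prob = numeric(0)))
  }
  neg <- labels[labels$label == "negative", c("article_id", "topic_id")]
  purrr::map_dfr(sort(unique(scores$topic_id)), function(t) {
    st <- scores[scores$topic_id == t, , drop = FALSE]
    st <- st[st$article_id %in% neg$article_id[neg$topic_id == t], , drop = FALSE]
    if (nrow(st) < k) {
      warn(sprintf("topic %s: only %d rule-negative articles available (k = %d)",
                   t, nrow(st), k))
    }
    ord <- order(-st$prob, seq_len(nrow(st)))
    take <- utils::head(ord, k)
    tibble::tibble(topic_id = t, rank = seq_along(take),
                   article_id = st$article_id[take], prob = st$prob[take])
  })
}

#' Hybrid inference filter over predicted probabilities
#'
#' Per topic, keeps the union of (a) articles with probability above
#' `threshold` and (b) the top `multiplier * N` articles by probability,
#' where `N` is the topic's rules-positive count. Reason flags record which
#' clause admitted each article.
#'
#' @param scores Long tibble `article_id`, `topic_id`, `prob`.
#' @param rules_positive_counts Named numeric vector or tibble
#'   (`topic_id`, `n_positive`) giving `N` per topic.
#' @param threshold Probability threshold (default 0.95).
#' @param multiplier Rank-band multiplier (default 3).
#' @return A tibble `topic_id`, `article_id`, `prob`, `above_threshold`,
#'   `within_rank_band`.
#' @export
apply_inference_filter <- function(scores, rules_positive_counts,
                                   threshold = 0.95, multiplier = 3L) {
  counts <- if (is.data.frame(rules_positive_counts)) {
    setNames(rules_positive_counts$n_positive,
             as.character(rules_positive_counts$topic_id))
  } else {
    setNames(as.numeric(rules_positive_counts), names(rules_positive_counts))
  }
  purrr::map_dfr(sort(unique(scores$topic_id)), function(t) {
    st <- scores[scores$topic_id == t, , drop = FALSE]
    n_t <- counts[[as.character(t)]] %||% 0
    band <- multiplier * n_t
    ord <- order(-st$prob, seq_len(nrow(st)))
    in_band <- logical(nrow(st))
    if (band > 0) in_band[utils::head(ord, band)] <- TRUE
    above <- st$prob > threshold
    keep <- above | in_band
    tibble::tibble(topic_id = t,
                   article_id = st$article_id[keep],
                   prob = st$prob[keep],
                   above_threshold = above[keep],
                   within_rank_band = in_band[keep])
  })
}
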