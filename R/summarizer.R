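#' Greedy ROUGE-1 oracle label construction
#'
#' Converts abstractive highlights (bullet points) into extractive labels:
#' for each highlight in order, selects the not-yet-selected source sentence
#' maximizing ROUGE-1 with it (F1 by default; ties go to the earliest
#' sentence). Already-selected sentences are skipped, so the result has at
#' most one source index per highlight.
#'
#' @param source_sentences Character vector of source sentences (nonempty).
#' @param highlights Character vector of highlight sentences (nonempty).
#' @param metric `"f1"` (default) or `"recall"` — the ROUGE-1 variant
#'   maximized at each greedy step.
#' @return Sorted integer vector of selected 0-based source indices.
#' @export
greedy_oracle_labels <- function(source_sentences, highlights,
                                 metric = c("f1", "recall")) {
  metric <- match.arg(metric)
  if (length(source_sentences) == 0) {
    validation_error("source sentence list is empty")
  }
  if (length(highlights) == 0) validation_error("highlight list is empty")
  selected <- integer(0)
  for (h in highlights) {
    avail <- setdiff(seq_along(source_sentences), selected)
    if (length(avail) == 0) break
    scores <- vapply(avail, function(i) {
      rouge1_variant(source_sentences[i], h, metric)
    }, numeric(1))
    best <- avail[which.max(scores)]  # which.max takes the earliest on ties
    selected <- c(selected, best)
  }
  sort(selected) - 1L
}

rouge1_variant <- function(candidate, reference, metric) {
  if (metric == "f1") return(rouge_n(candidate, reference, 1L))
  ct <- tokenize1(candidate); rt <- tokenize1(reference)
  if (length(ct) == 0 || length(rt) == 0) return(0)
  ctab <- table(ct); rtab <- table(rt)
  shared <- intersect(names(ctab), names(rtab))
  100 * sum(pmin(ctab[shared], rtab[shared])) / length(rt)
}

#' Merge rule pseudolabels and human annotations into training labels
#'
#' Each article may carry a *global* label (1–3 sentence indices selected by
#' a human annotator as a global extractive summary) and/or a *topic* label
#' (sentences matched by sentence-scope rules). Articles with neither source
#' are excluded. Out-of-range indices and human selections of more than 3
#' sentences are validation errors naming the article.
#'
#' @param rule_matches Tibble from [classify_corpus()] (`matched_sentences`
#'   of passing topics become topic labels).
#' @param human_annotations Tibble with `article_id` and `selected_indices`
#'   (list-column of 0-based indices), or `NULL`.
#' @param sentences Sentence index used for range validation ([segment_corpus()]).
#' @return A tibble `article_id`, `global_indices`, `topic_indices`
#'   (list-columns; `NULL` entries mean the source is absent).
#' @export
build_training_labels <- function(rule_matches, human_annotations, sentences) {
  n_sent <- table(sentences$article_id)
  topic_lab <- NULL
  if (!is.null(rule_matches) && nrow(rule_matches) > 0) {
    pass <- rule_matches[rule_matches$passed, , drop = FALSE]
    if (nrow(pass) > 0) {
      topic_lab <- pass |>
        dplyr::group_by(.data$article_id) |>
        dplyr::summarise(topic_indices = list(sort(unique(unlist(.data$matched_sentences)))),
                         .groups = "drop")
      topic_lab <- topic_lab[vapply(topic_lab$topic_indices, length, integer(1)) > 0, ]
    }
  }
  human_lab <- NULL
  if (!is.null(human_annotations) && nrow(human_annotations) > 0) {
    for (i in seq_len(nrow(human_annotations))) {
      idx <- human_annotations$selected_indices[[i]]
      id <- human_annotations$article_id[i]
      if (length(idx) < 1 || length(idx) > 3) {
        validation_error("article '%s': human selection must have 1-3 sentences, got %d",
                         id, length(idx))
      }
      ns <- as.integer(n_sent[id] %||% 0L)
      if (any(idx < 0) || any(idx >= ns)) {
        validation_error("article '%s': sentence index out of range", id)
      }
    }
    human_lab <- tibble::tibble(
      article_id = human_annotations$article_id,
      global_indices = lapply(human_annotations$selected_indices,
                              function(x) sort(as.integer(x)))
    )
  }
  ids <- union(if (is.null(human_lab)) character(0) else human_lab$article_id,
               if (is.null(topic_lab)) character(0) else topic_lab$article_id)
  if (length(ids) == 0) {
    return(tibble::tibble(article_id = character(0),
                          global_indices = list(), topic_indices = list()))
  }
  out <- tibble::tibble(article_id = ids)
  out$global_indices <- lapply(ids, function(id) {
    if (!is.null(human_lab) && id %in% human_lab$article_id) {
      human_lab$global_indices[[match(id, human_lab$article_id)]]
    } else NULL
  })
  out$topic_indices <- lapply(ids, function(id) {
    if (!is.null(topic_lab) && id %in% topic_lab$article_id) {
      idx <- topic_lab$topic_indices[[match(id, topic_lab$article_id)]]
      ns <- as.integer(n_sent[id] %||% 0L)
      if (any(idx < 0) || any(idx >= ns)) {
        validation_error("article '%s': rule-matched sentence index out of range", id)
      }
      as.integer(idx)
    } else NULL
  })
  out
}

#' Training configuration for the dual-head summarizer
#'
#' Defaults mirror the summarizer fine-tuning schedule: 10 epochs, Adam at
#' 1e-5, warmup over the first 10% of steps then linear decay, evaluation
#' every epoch with early stopping (checkpoint on improvement) on validation
#' mean ROUGE.
#'
#' @inheritParams classifier_config
#' @return A list of class `nw_train_config`.
#' @export
summarizer_config <- function(epochs = 10L, learning_rate = 1e-5,
                              batch_size = 16L, warmup_frac = 0.10,
                              hidden = 64L, seed = 1L) {
  stopifnot(epochs >= 0, learning_rate > 0, batch_size >= 1,
            warmup_frac > 0, warmup_frac < 1, hidden >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), warmup_frac = warmup_frac,
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "nw_train_config")
}

# assemble per-sentence features/targets/masks for the labelled articles
summarizer_design <- function(sentences, labels, encoder) {
  keep <- sentences[sentences$article_id %in% labels$article_id, , drop = FALSE]
  X <- encode_texts(encoder, keep$text)
  Y <- matrix(0, nrow(keep), 2L, dimnames = list(NULL, c("global", "topic")))
  M <- matrix(0, nrow(keep), 2L)
  for (i in seq_len(nrow(labels))) {
    rows <- which(keep$article_id == labels$article_id[i])
    gi <- labels$global_indices[[i]]
    ti <- labels$topic_indices[[i]]
    if (!is.null(gi)) {
      M[rows, 1L] <- 1
      Y[rows[keep$sentence[rows] %in% gi], 1L] <- 1
    }
    if (!is.null(ti)) {
      M[rows, 2L] <- 1
      Y[rows[keep$sentence[rows] %in% ti], 2L] <- 1
    }
  }
  list(sentences = keep, X = X, Y = Y, M = M)
}

#' Train the dual-head extractive sentence scorer
#'
#' Every sentence of a labelled article is encoded and scored by a shared
#' hidden layer with two sigmoid output heads: one predicting membership in
#' the human *global* summary, one predicting membership in the rule-derived
#' *topic* pseudosummary. The loss is per-head binary cross-entropy, and a
#' head's term is masked out entirely for articles lacking that label source,
#' so an absent source contributes exactly zero gradient. Validation (when
#' `val_ids` are supplied) computes the mean of ROUGE-1/2/L between each
#' article's predicted top-3 summary and its human-selected sentences, and
#' the best checkpoint is kept.
#'
#' @param corpus A corpus tibble.
#' @param sentences Sentence index for the corpus.
#' @param labels Labels from [build_training_labels()] (at least one row).
#' @param val_ids Optional article ids (with global labels) held out for
#'   validation ROUGE; they are excluded from training.
#' @param encoder Deterministic sentence encoder (default
#'   [hashing_encoder()]).
#' @param config A [summarizer_config()].
#' @return An object of class `nw_summarizer`.
#' @export
train_summarizer <- function(corpus, sentences, labels, val_ids = NULL,
                             encoder = hashing_encoder(),
                             config = summarizer_config()) {
  if (nrow(labels) == 0) {
    abort("no summarization labels: summarizer is untrainable",
          class = "newswatch_training_error")
  }
  val_labels <- labels[labels$article_id %in% (val_ids %||% character(0)), , drop = FALSE]
  tr_labels <- labels[!labels$article_id %in% (val_ids %||% character(0)), , drop = FALSE]
  if (nrow(tr_labels) == 0) {
    abort("all labelled articles assigned to validation",
          class = "newswatch_training_error")
  }
  ds <- summarizer_design(sentences, tr_labels, encoder)
  params <- mlp_init(encoder_dim(encoder), config$hidden, 2L,
                     seed = derive_seed(config$seed, "sum_init"))
  steps_per_epoch <- max(1L, ceiling(nrow(ds$X) / config$batch_size))
  loop_config <- list(epochs = config$epochs, learning_rate = config$learning_rate,
                      batch_size = config$batch_size, warmup_frac = config$warmup_frac,
                      eval_every = steps_per_epoch, seed = config$seed)
  eval_fn <- NULL
  if (nrow(val_labels) > 0) {
    has_global <- !vapply(val_labels$global_indices, is.null, logical(1))
    val_labels <- val_labels[has_global, , drop = FALSE]
  }
  if (nrow(val_labels) > 0) {
    vsent <- sentences[sentences$article_id %in% val_labels$article_id, , drop = FALSE]
    Xv <- encode_texts(encoder, vsent$text)
    eval_fn <- function(p) {
      P <- mlp_forward(p, Xv)$P
      mean(vapply(seq_len(nrow(val_labels)), function(i) {
        rows <- which(vsent$article_id == val_labels$article_id[i])
        sel <- rows[select_top_k(P[rows, 1] + P[rows, 2], 3L)]
        ref_rows <- rows[vsent$sentence[rows] %in% val_labels$global_indices[[i]]]
        rouge_mean(paste(vsent$text[sort(sel)], collapse = " "),
                   paste(vsent$text[ref_rows], collapse = " "))
      }, numeric(1)))
    }
  }
  fit <- train_mlp_loop(params, ds$X, ds$Y, ds$M, loop_config, eval_fn = eval_fn)
  val_rouge <- if (!is.null(eval_fn)) eval_fn(fit$best_params) else NA_real_
  structure(list(
    params = fit$best_params,
    encoder = encoder,
    config = config,
    history = fit$history,
    val_rouge = val_rouge,
    n_train_articles = nrow(tr_labels)
  ), class = "nw_summarizer")
}

# indices (within the score vector) of the top-k scores, ties to earlier
select_top_k <- function(score, k) {
  utils::head(order(-score, seq_along(score)), min(k, length(score)))
}

#' Score each sentence of an article with the dual head
#'
#' @param model An `nw_summarizer`.
#' @param sentences Sentence index rows for one or more articles.
#' @return The sentence tibble with `p_global` and `p_topic` columns added.
#' @export
score_sentences <- function(model, sentences) {
  if (nrow(sentences) == 0) {
    sentences$p_global <- numeric(0)
    sentences$p_topic <- numeric(0)
    return(sentences)
  }
  P <- mlp_forward(model$params, encode_texts(model$encoder, sentences$text))$P
  sentences$p_global <- P[, 1]
  sentences$p_topic <- P[, 2]
  sentences
}

#' Emit a k-sentence extractive summary for one article
#'
#' Sentences are ranked by decreasing `p_global + p_topic` (ties to the
#' earlier sentence); the top `min(k, n)` are selected and emitted verbatim
#' in original document order, with the rank kept as metadata.
#'
#' @param model An `nw_summarizer`.
#' @param article One-row corpus tibble.
#' @param sentences Sentence index for the article.
#' @param k Summary size (default 3).
#' @return A tibble `article_id`, `sentence`, `rank`, `p_global`, `p_topic`,
#'   `text`, ordered by document position. Empty article gives zero rows.
#' @export
summarize_article <- function(model, article, sentences, k = 3L) {
  sn <- sentences[sentences$article_id == article$article_id[[1]], , drop = FALSE]
  sc <- score_sentences(model, sn)
  if (nrow(sc) == 0) {
    return(tibble::tibble(article_id = character(0), sentence = integer(0),
                          rank = integer(0), p_global = numeric(0),
                          p_topic = numeric(0), text = character(0)))
  }
  sel <- select_top_k(sc$p_global + sc$p_topic, k)
  out <- sc[sel, , drop = FALSE]
  out$rank <- seq_along(sel)
  out <- out[order(out$sentence), , drop = FALSE]
  out[, c("article_id", "sentence", "rank", "p_global", "p_topic", "text")]
}

#' Summarize every article in a corpus
#'
#' @param model An `nw_summarizer`.
#' @param corpus A corpus tibble.
#' @param sentences Sentence index for the corpus.
#' @param k Summary size (default 3).
#' @return One tibble of summaries (see [summarize_article()]).
#' @export
summarize_corpus <- function(model, corpus, sentences, k = 3L) {
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    summarize_article(model, corpus[i, , drop = FALSE], sentences, k = k)
  })
}

#' Evaluate predicted summaries against references
#'
#' Per-article ROUGE-1, ROUGE-2 and ROUGE-L F1 (x100) and their mean, plus
#' overall (and, when a `topic_id` column is present, per-topic) means.
#' Articles with an empty reference are skipped with a warning.
#'
#' @param predictions Tibble with `article_id` and `summary` (text), and
#'   optionally `topic_id`.
#' @param references Tibble with `article_id` and `summary` (text).
#' @return An object of class `nw_rouge_eval`: list with `per_article`,
#'   `overall` (one row: `rouge1`, `rouge2`, `rougeL`, `mean_rouge`), and
#'   `by_topic` (or `NULL`).
#' @export
evaluate_summaries <- function(predictions, references) {
  stopifnot(all(c("article_id", "summary") %in% names(predictions)),
            all(c("article_id", "summary") %in% names(references)))
  merged <- dplyr::inner_join(predictions, references, by = "article_id",
                              suffix = c("_pred", "_ref"))
  empty_ref <- !nzchar(trimws(merged$summary_ref))
  if (any(empty_ref)) {
    warn(sprintf("%d article(s) skipped: empty reference summary", sum(empty_ref)))
    merged <- merged[!empty_ref, , drop = FALSE]
  }
  per_article <- purrr::map_dfr(seq_len(nrow(merged)), function(i) {
    r1 <- rouge_n(merged$summary_pred[i], merged$summary_ref[i], 1L)
    r2 <- rouge_n(merged$summary_pred[i], merged$summary_ref[i], 2L)
    rl <- rouge_l(merged$summary_pred[i], merged$summary_ref[i])
    tibble::tibble(article_id = merged$article_id[i],
                   rouge1 = r1, rouge2 = r2, rougeL = rl,
                   mean_rouge = mean(c(r1, r2, rl)))
  })
  if ("topic_id" %in% names(merged) && nrow(per_article) > 0) {
    per_article$topic_id <- merged$topic_id
  }
  overall <- tibble::tibble(
    rouge1 = mean(per_article$rouge1),
    rouge2 = mean(per_article$rouge2),
    rougeL = mean(per_article$rougeL),
    mean_rouge = mean(per_article$mean_rouge)
  )
  by_topic <- NULL
  if ("topic_id" %in% names(per_article)) {
    by_topic <- per_article |>
      dplyr::group_by(.data$topic_id) |>
      dplyr::summarise(dplyr::across(c("rouge1", "rouge2", "rougeL", "mean_rouge"),
                                     mean), .groups = "drop")
  }
  structure(list(per_article = per_article, overall = overall,
                 by_topic = by_topic), class = "nw_rouge_eval")
}

#' @export
print.nw_rouge_eval <- function(x, ...) {
  cat(sprintf("Summary evaluation over %d articles\n", nrow(x$per_article)))
  print(x$overall)
  invisible(x)
}

#' @describeIn evaluate_summaries `tidy()` returns per-article scores.
#' @param x An `nw_rouge_eval`.
#' @param ... Unused.
#' @export
tidy.nw_rouge_eval <- function(x, ...) x$per_article

#' @describeIn evaluate_summaries `glance()` returns the overall means.
#' @export
glance.nw_rouge_eval <- function(x, ...) x$overall

#' @describeIn train_summarizer `tidy()` returns the training history.
#' @param x An `nw_summarizer`.
#' @param ... Unused.
#' @export
tidy.nw_summarizer <- function(x, ...) x$history

#' @describeIn train_summarizer `glance()` returns a one-row model summary.
#' @export
glance.nw_summarizer <- function(x, ...) {
  tibble::tibble(
    n_train_articles = x$n_train_articles,
    hidden = x$config$hidden,
    epochs = x$config$epochs,
    val_mean_rouge = x$val_rouge
  )
}
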