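#' Pipeline configuration
#'
#' Stage toggles and stage configurations for [run_pipeline()]. One global
#' seed deterministically derives the per-stage seeds (split, training,
#' generation), so a rerun with identical inputs and configuration
#' reproduces identical outputs given deterministic encoders.
#'
#' @param dedup,language_filter,rules,classifier,country,summarize Stage
#'   toggles (rules is mandatory and always on).
#' @param classifier_config A [classifier_config()].
#' @param summarizer_config A [summarizer_config()].
#' @param split A [split_spec()] for classifier training.
#' @param threshold,multiplier Inference-filter parameters (see
#'   [apply_inference_filter()]).
#' @param enrichment_k Size of the per-topic enrichment review list written
#'   by the classifier stage (default 500).
#' @param keep_language Language retained by the language filter.
#' @param encoder Shared deterministic encoder for classifier, summarizer
#'   and country assignment.
#' @param seed Global seed.
#' @return A list of class `nw_pipeline_config`.
#' @export
pipeline_config <- function(dedup = TRUE, language_filter = TRUE,
                            rules = TRUE, classifier = TRUE, country = TRUE,
                            summarize = TRUE,
                            classifier_config = newswatch::classifier_config(
                              epochs = 3L, eval_every = 200L, hidden = 64L),
                            summarizer_config = newswatch::summarizer_config(
                              epochs = 5L),
                            split = split_spec(),
                            threshold = 0.95, multiplier = 3L,
                            enrichment_k = 500L, keep_language = "en",
                            encoder = hashing_encoder(), seed = 1L) {
  if (!rules) validation_error("the rules stage is mandatory")
  structure(list(
    dedup = dedup, language_filter = language_filter, rules = rules,
    classifier = classifier, country = country, summarize = summarize,
    classifier_config = classifier_config, summarizer_config = summarizer_config,
    split = split, threshold = threshold, multiplier = as.integer(multiplier),
    enrichment_k = as.integer(enrichment_k), keep_language = keep_language,
    encoder = encoder, seed = as.integer(seed)
  ), class = "nw_pipeline_config")
}

config_fingerprint <- function(config) {
  plain <- config[!vapply(config, is.function, logical(1))]
  plain <- lapply(plain, function(x) {
    if (is.list(x)) x[!vapply(x, is.function, logical(1))] else x
  })
  as.character(nw_hash(jsonlite::toJSON(plain, auto_unbox = TRUE, force = TRUE)))
}

#' Run the end-to-end surveillance pipeline
#'
#' Fixed stage order: deduplication, language filtering, rule-based topic
#' classification, classifier training and inference filtering, country
#' assignment, summarization, and grouping into per-(topic, country) pools.
#'
#' Pool membership: all rule positives of a topic, plus (when the classifier
#' stage is on) non-rule articles whose predicted probability exceeds the
#' threshold. The corpus-wide top `multiplier * N` band of the inference
#' filter is returned as an enrichment review artifact
#' (`result$enrichment`) for human relabelling rather than auto-admitted to
#' the pools, since without a human verdict that band is a deliberately
#' low-precision recall net. Every pooled article appears under exactly one
#' country per topic.
#'
#' @param corpus A corpus tibble or a path readable by [read_corpus()].
#' @param rulesets Named list of `nw_ruleset` (default [default_rulesets()]),
#'   or a path readable by [parse_ruleset()].
#' @param config A [pipeline_config()].
#' @param annotations Optional human summary annotations (tibble
#'   `article_id`, `selected_indices`) folded into summarizer training.
#' @param out_dir Optional directory: writes `pools.jsonl`, `manifest.json`
#'   and report CSVs atomically.
#' @return An object of class `nw_pipeline_result`: `pools` (tibble
#'   `topic_id`, `country`, `article_id`, `prob`, `summary`), `manifest`,
#'   `rule_labels`, `rule_report`, `scores`, `enrichment`, `countries`,
#'   `classifier`, `summarizer`.
#' @export
run_pipeline <- function(corpus, rulesets = default_rulesets(),
                         config = pipeline_config(), annotations = NULL,
                         out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(corpus)) {
    if (!file.exists(corpus)) {
      abort(sprintf("missing corpus file '%s'", corpus), class = "newswatch_io_error")
    }
    corpus <- read_corpus(corpus)
  }
  if (is.character(rulesets)) {
    if (!file.exists(rulesets)) {
      abort(sprintf("missing rules file '%s'", rulesets), class = "newswatch_io_error")
    }
    rulesets <- parse_ruleset(rulesets)
  }
  validate_corpus(corpus)
  stages <- list(list(stage = "input", n = nrow(corpus)))

  if (config$dedup) {
    corpus <- suppressMessages(deduplicate_by_title(corpus))
    stages <- c(stages, list(list(stage = "dedup", n = nrow(corpus))))
  }
  if (config$language_filter) {
    corpus <- suppressMessages(filter_language(corpus, keep = config$keep_language))
    stages <- c(stages, list(list(stage = "language_filter", n = nrow(corpus))))
  }
  sentences <- segment_corpus(corpus)
  rule_labels <- classify_corpus(corpus, rulesets, sentences)
  report <- rule_report(rule_labels)
  stages <- c(stages, list(list(stage = "rules", n = sum(rule_labels$passed))))

  scores <- NULL; enrichment <- NULL; clf <- NULL
  kept <- rule_labels[rule_labels$passed, c("topic_id", "article_id")]
  kept$prob <- NA_real_
  if (config$classifier && nrow(corpus) > 0 && sum(rule_labels$passed) > 0) {
    store <- labels_from_rules(rule_labels)
    split <- config$split
    split$seed <- derive_seed(config$seed, "split")
    ds <- build_datasets(corpus, store, split)
    cc <- config$classifier_config
    cc$seed <- derive_seed(config$seed, "classifier")
    clf <- suppressWarnings(
      train_classifier(ds$train, ds$val, encoder = config$encoder, config = cc))
    scores <- predict(clf, corpus)
    enrichment <- suppressWarnings(
      select_enrichment_candidates(scores, store, k = config$enrichment_k))
    high <- scores[scores$prob > config$threshold, , drop = FALSE]
    rules_pos_key <- paste(kept$topic_id, kept$article_id)
    add <- high[!paste(high$topic_id, high$article_id) %in% rules_pos_key, , drop = FALSE]
    prob_of <- setNames(scores$prob, paste(scores$topic_id, scores$article_id))
    kept$prob <- unname(prob_of[rules_pos_key])
    kept <- dplyr::bind_rows(kept,
                             tibble::tibble(topic_id = add$topic_id,
                                            article_id = add$article_id,
                                            prob = add$prob))
    stages <- c(stages, list(list(stage = "classifier_filter", n = nrow(kept))))
  }

  countries <- NULL
  if (config$country && nrow(kept) > 0) {
    pool_articles <- corpus[corpus$article_id %in% unique(kept$article_id), , drop = FALSE]
    countries <- assign_countries(pool_articles, sentences,
                                  encoder = config$encoder)
    stages <- c(stages, list(list(stage = "country", n = nrow(countries))))
  }

  summarizer <- NULL
  summaries <- NULL
  if (config$summarize && nrow(kept) > 0) {
    labels <- build_training_labels(rule_labels, annotations, sentences)
    if (nrow(labels) > 0) {
      sc <- config$summarizer_config
      sc$seed <- derive_seed(config$seed, "summarizer")
      summarizer <- train_summarizer(corpus, sentences, labels,
                                     encoder = config$encoder, config = sc)
      pool_articles <- corpus[corpus$article_id %in% unique(kept$article_id), , drop = FALSE]
      summ <- summarize_corpus(summarizer, pool_articles, sentences)
      summaries <- summ |>
        dplyr::group_by(.data$article_id) |>
        dplyr::summarise(summary = paste(.data$text, collapse = " "), .groups = "drop")
      stages <- c(stages, list(list(stage = "summarize", n = nrow(summaries))))
    }
  }

  pools <- kept
  pools$country <- if (!is.null(countries)) {
    countries$country[match(pools$article_id, countries$article_id)]
  } else {
    NA_character_
  }
  pools$summary <- if (!is.null(summaries)) {
    summaries$summary[match(pools$article_id, summaries$article_id)]
  } else {
    NA_character_
  }
  pools <- pools[order(pools$topic_id, pools$country, pools$article_id),
                 c("topic_id", "country", "article_id", "prob", "summary")]
  pools <- tibble::as_tibble(pools)

  manifest <- list(
    stages = stages,
    seed = config$seed,
    config_hash = config_fingerprint(config),
    n_pools = nrow(pools),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  result <- structure(list(
    pools = pools, manifest = manifest, rule_labels = rule_labels,
    rule_report = report, scores = scores, enrichment = enrichment,
    countries = countries, classifier = clf, summarizer = summarizer
  ), class = "nw_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.nw_pipeline_result <- function(x, ...) {
  cat("Pipeline run\n")
  for (s in x$manifest$stages) cat(sprintf("  %-18s %d\n", s$stage, s$n))
  cat(sprintf("Pools: %d (topic, article) entries\n", nrow(x$pools)))
  invisible(x)
}

# atomic write helper: write to a temp file in the same directory, then rename
write_atomic <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  write_fn(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_atomic(function(p) {
    lines <- vapply(seq_len(nrow(result$pools)), function(i) {
      jsonlite::toJSON(as.list(result$pools[i, ]), auto_unbox = TRUE, na = "null")
    }, character(1))
    writeLines(lines, p)
  }, file.path(out_dir, "pools.jsonl"))
  write_atomic(function(p) {
    jsonlite::write_json(result$manifest, p, auto_unbox = TRUE, pretty = TRUE)
  }, file.path(out_dir, "manifest.json"))
  tables <- export_report_tables(result)
  for (nm in names(tables)) {
    write_atomic(function(p) readr::write_csv(tables[[nm]], p, progress = FALSE),
                 file.path(out_dir, paste0(nm, ".csv")))
  }
  invisible(out_dir)
}

#' Export report-style tables from a pipeline run
#'
#' Three tables mirroring standard surveillance-report bookkeeping:
#' per-topic rule positives, rates and the symmetric topic-overlap matrix
#' (diagonal `NA`); classifier ranking metrics (ROC-AUC, PR-AUC,
#' precision/recall at 2N and 10N) against the rule labels; and per-topic
#' ROUGE means when a summary evaluation is supplied. Mean rows are
#' recomputed from the per-topic values (rounded to 2 decimals); metrics
#' undefined for a topic (single-class labels) are rendered `NA`.
#'
#' @param result An `nw_pipeline_result`.
#' @param rouge_eval Optional `nw_rouge_eval` with a `by_topic` element.
#' @return Named list of tibbles: `table_rules`, `table_classifier`,
#'   `table_rouge`.
#' @export
export_report_tables <- function(result, rouge_eval = NULL) {
  rep <- result$rule_report
  topics <- rep$topics
  ov <- as.data.frame(rep$overlap)
  t1 <- dplyr::bind_cols(topics, tibble::as_tibble(ov))
  mean_row <- tibble::tibble(
    topic_id = NA_integer_,
    n_positive = round(mean(topics$n_positive), 2),
    rate_pct = round(mean(topics$rate_pct), 2)
  )
  for (nm in names(ov)) mean_row[[nm]] <- NA_integer_
  t1 <- dplyr::bind_rows(t1, mean_row)

  t2 <- tibble::tibble(topic_id = topics$topic_id, roc_auc = NA_real_,
                       pr_auc = NA_real_, prec_at_2n = NA_real_,
                       prec_at_10n = NA_real_, rec_at_2n = NA_real_,
                       rec_at_10n = NA_real_)
  if (!is.null(result$scores)) {
    truth <- result$rule_labels
    for (i in seq_len(nrow(t2))) {
      t <- t2$topic_id[i]
      st <- result$scores[result$scores$topic_id == t, , drop = FALSE]
      y <- truth$passed[match(paste(st$article_id, t),
                              paste(truth$article_id, truth$topic_id))]
      n_t <- sum(y)
      if (n_t == 0 || n_t == length(y)) next
      t2$roc_auc[i] <- 100 * roc_auc(st$prob, y)
      t2$pr_auc[i] <- 100 * pr_auc(st$prob, y)
      for (k in c(2L, 10L)) {
        m <- min(k * n_t, length(y))
        t2[[paste0("prec_at_", k, "n")]][i] <- 100 * precision_at(st$prob, y, m)
        t2[[paste0("rec_at_", k, "n")]][i] <- 100 * recall_at(st$prob, y, m)
      }
    }
  }
  t2_mean <- t2 |>
    dplyr::summarise(dplyr::across(-"topic_id", ~round(mean(.x, na.rm = TRUE), 2)))
  t2 <- dplyr::bind_rows(t2, dplyr::bind_cols(tibble::tibble(topic_id = NA_integer_), t2_mean))

  t3 <- tibble::tibble(topic_id = topics$topic_id, mean_rouge = NA_real_)
  if (!is.null(rouge_eval) && !is.null(rouge_eval$by_topic)) {
    t3$mean_rouge <- rouge_eval$by_topic$mean_rouge[
      match(t3$topic_id, rouge_eval$by_topic$topic_id)]
  }
  t3 <- dplyr::bind_rows(t3, tibble::tibble(
    topic_id = NA_integer_,
    mean_rouge = round(mean(t3$mean_rouge, na.rm = TRUE), 2)))

  list(table_rules = t1, table_classifier = t2, table_rouge = t3)
}
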