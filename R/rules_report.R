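#' Summarize rule-based classification of a corpus
#'
#' Bookkeeping over the output of [classify_corpus()]: per-topic positive
#' counts and rates (% of the corpus), the symmetric pairwise overlap counts
#' (diagonal `NA` by convention), and the cross-topic mean positive rate.
#'
#' @param labels Tibble from [classify_corpus()].
#' @param n_articles Corpus size used as the rate denominator; defaults to
#'   the `n_articles` attribute recorded by [classify_corpus()].
#' @return An object of class `nw_rule_report` with elements `topics`
#'   (tibble: `topic_id`, `n_positive`, `rate_pct`), `overlap` (integer
#'   matrix), `mean_rate_pct` and `n_articles`.
#' @export
rule_report <- function(labels, n_articles = attr(labels, "n_articles")) {
  if (is.null(n_articles)) {
    n_articles <- length(unique(labels$article_id))
  }
  topic_ids <- sort(unique(labels$topic_id))
  pos <- labels[labels$passed, c("article_id", "topic_id")]
  counts <- vapply(topic_ids, function(t) sum(pos$topic_id == t), integer(1))
  topics <- tibble::tibble(
    topic_id = topic_ids,
    n_positive = counts,
    rate_pct = if (n_articles > 0) 100 * counts / n_articles else rep(NA_real_, length(counts))
  )
  k <- length(topic_ids)
  overlap <- matrix(NA_integer_, k, k)
  if (k > 0) {
    dimnames(overlap) <- list(paste0("topic_", topic_ids),
                              paste0("topic_", topic_ids))
  }
  pos_sets <- lapply(topic_ids, function(t) pos$article_id[pos$topic_id == t])
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a != b) overlap[a, b] <- length(intersect(pos_sets[[a]], pos_sets[[b]]))
  }
  structure(list(
    topics = topics,
    overlap = overlap,
    mean_rate_pct = mean(topics$rate_pct),
    n_articles = n_articles
  ), class = "nw_rule_report")
}

#' @export
print.nw_rule_report <- function(x, ...) {
  cat(sprintf("Rule-based classification report over %d articles\n", x$n_articles))
  print(x$topics)
  cat(sprintf("Mean positive rate: %.3f%%\n", x$mean_rate_pct))
  invisible(x)
}

#' @describeIn rule_report `tidy()` returns the per-topic tibble.
#' @param x An `nw_rule_report`.
#' @param ... Unused.
#' @export
tidy.nw_rule_report <- function(x, ...) x$topics

#' @describeIn rule_report `glance()` returns a one-row summary.
#' @export
glance.nw_rule_report <- function(x, ...) {
  tibble::tibble(
    n_articles = x$n_articles,
    n_topics = nrow(x$topics),
    total_positive = sum(x$topics$n_positive),
    mean_rate_pct = x$mean_rate_pct
  )
}

#' @describeIn rule_report `autoplot()` draws per-topic positive rates.
#' @param object An `nw_rule_report`.
#' @export
autoplot.nw_rule_report <- function(object, ...) {
  ggplot2::ggplot(object$topics,
                  ggplot2::aes(x = factor(.data$topic_id), y = .data$rate_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Topic", y = "Positive rate (%)",
                  title = "Rule-based positive rate per topic") +
    ggplot2::theme_minimal()
}
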