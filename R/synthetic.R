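#' Illustrative topic keyword vocabularies
#'
#' Six health-workforce surveillance topics with disjoint keyword
#' vocabularies: (1) workforce policy and investment, (2) health-worker
#' education, (3) health-worker vaccination, (4) strikes and industrial
#' actions, (5) health-worker mental health, (6) health-worker infections
#' and deaths. These are illustrative defaults — real deployments supply
#' their own expert-curated rule files — but they are the single source of
#' truth shared by [default_rulesets()] and the synthetic generator, so
#' generated positives pass their topic's rules by construction.
#'
#' @return Named list of character vectors, names `topic_1` .. `topic_6`.
#' @export
topic_vocabularies <- function() {
  list(
    topic_1 = c("workforce", "policy", "investment", "funding", "recruitment", "staffing"),
    topic_2 = c("education", "training", "curriculum", "trainees", "graduates", "coursework"),
    topic_3 = c("vaccination", "vaccine", "immunization", "doses", "booster", "jab"),
    topic_4 = c("strike", "walkout", "picket", "industrial", "unions", "stoppage"),
    topic_5 = c("burnout", "anxiety", "depression", "stress", "wellbeing", "exhaustion"),
    topic_6 = c("infections", "deaths", "infected", "mortality", "fatalities", "died")
  )
}

topic_names <- function() {
  c("workforce policy and investment", "health-worker education",
    "health-worker vaccination", "strikes and industrial actions",
    "health-worker mental health", "health-worker infections and deaths")
}

exclusion_keywords <- function() c("sports", "football", "celebrity")

#' Illustrative default rule sets for the six topics
#'
#' Each topic's rule set is the conjunction of (a) a sentence-scope match
#' requiring at least 2 distinct topic keywords in one sentence and (b) an
#' exclusion rule discarding articles mentioning off-topic noise keywords.
#' Clearly non-authoritative: supply expert rule files for real use.
#'
#' @return Named list of `nw_ruleset`.
#' @export
default_rulesets <- function() {
  vocab <- topic_vocabularies()
  nms <- topic_names()
  out <- lapply(seq_along(vocab), function(t) {
    topic_ruleset(t, nms[t], list(
      rule_match("sentence", vocab[[t]], min_distinct = 2L),
      rule_not(rule_match("body", exclusion_keywords(), min_distinct = 1L))
    ))
  })
  setNames(out, paste0("topic_", seq_along(vocab)))
}

background_vocabulary <- function() {
  c("hospital", "reported", "local", "community", "officials", "meeting",
    "services", "patients", "care", "public", "support", "plans", "city",
    "region", "measures", "update", "response", "team", "ministry", "board",
    "clinic", "staff", "week", "announcement", "review", "figures")
}

non_english_vocabulary <- function() {
  c("krankenhaus", "bericht", "gemeinde", "beamte", "sitzung", "dienste",
    "patienten", "pflege", "stadt", "massnahmen", "antwort", "ministerium",
    "woche", "zahlen", "bericht", "und", "nicht", "eine", "wurde", "heute")
}

#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical shape of a large epidemic-
#' intelligence news extract at desk scale: rare per-topic positives carrying
#' keyword-bearing key sentences, background noise articles, exact-title
#' duplicate groups, planted country mentions, a small non-English
#' contamination, and simulated annotators with controllable agreement.
#'
#' @param n_articles Total number of articles (including duplicates).
#' @param prevalence Per-topic positive probability; scalar or length-6
#'   vector. Default 0.01 (tests); large-scale realism runs use ~0.0005.
#' @param n_topics Number of topics (default 6).
#' @param sentences_range Min/max sentences per article body.
#' @param duplicate_frac Fraction of articles that are exact-title duplicates
#'   of an earlier article (default 0.05).
#' @param country_pool Candidate country codes (must exist in the packaged
#'   gazetteer).
#' @param mention_prob Probability that an article's true country is named in
#'   its title (default 0.7; otherwise assignment must fall back to the
#'   embedding route).
#' @param non_english_frac Fraction of planted non-English articles
#'   (default 0.002, mirroring a ~99.8%-English corpus).
#' @param annotator_r Number of simulated raters (default 3).
#' @param agreement Probability a rater copies the ground-truth key-sentence
#'   selection instead of choosing at random (default 0.8).
#' @param highlight_dropout Token-dropout rate for generated highlights
#'   (default 0.1).
#' @param vocab_overlap Number of shared tokens appended to every topic
#'   vocabulary to stress cross-topic false positives (default 0).
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return A list of class `nw_synth_config`.
#' @export
synthetic_config <- function(n_articles = 1000L, prevalence = 0.01,
                             n_topics = 6L, sentences_range = c(5L, 12L),
                             duplicate_frac = 0.05,
                             country_pool = c("US", "GB", "FR", "DE", "IN",
                                              "KE", "BR", "AU", "JP", "ZA"),
                             mention_prob = 0.7, non_english_frac = 0.002,
                             annotator_r = 3L, agreement = 0.8,
                             highlight_dropout = 0.1, vocab_overlap = 0L,
                             seed = 1L) {
  if (length(prevalence) == 1L) prevalence <- rep(prevalence, n_topics)
  stopifnot(length(prevalence) == n_topics, all(prevalence >= 0), all(prevalence <= 1))
  assert_fraction(duplicate_frac, "duplicate_frac")
  assert_fraction(mention_prob, "mention_prob")
  assert_fraction(non_english_frac, "non_english_frac")
  assert_fraction(agreement, "agreement")
  assert_fraction(highlight_dropout, "highlight_dropout")
  stopifnot(annotator_r >= 2, n_articles >= 1,
            length(sentences_range) == 2, sentences_range[1] >= 2)
  structure(list(
    n_articles = as.integer(n_articles), prevalence = prevalence,
    n_topics = as.integer(n_topics), sentences_range = as.integer(sentences_range),
    duplicate_frac = duplicate_frac, country_pool = country_pool,
    mention_prob = mention_prob, non_english_frac = non_english_frac,
    annotator_r = as.integer(annotator_r), agreement = agreement,
    highlight_dropout = highlight_dropout, vocab_overlap = as.integer(vocab_overlap),
    seed = as.integer(seed)
  ), class = "nw_synth_config")
}

# one background sentence; function words guarantee the English detector fires
synth_sentence <- function(bg) {
  k <- sample(3:6, 1)
  w <- sample(bg, k, replace = TRUE)
  paste0("The ", w[1], " of the ", paste(w[-1], collapse = " "), ".")
}

# a key sentence for topic t: two distinct topic keywords in one sentence
synth_key_sentence <- function(kw, bg) {
  two <- sample(kw, 2)
  paste0("The ", two[1], " and the ", two[2], " for ",
         paste(sample(bg, 2, replace = TRUE), collapse = " "), ".")
}

#' Generate a synthetic corpus with ground truth
#'
#' Builds `n_articles` articles: per-topic positives (planted at the
#' configured prevalence) contain 1–2 key sentences bearing at least two
#' distinct topic keywords each — so they pass the shipped
#' [default_rulesets()] by construction — background articles draw from a
#' disjoint vocabulary, a configured fraction are exact-title duplicates of
#' earlier articles, the true country is named in the title with probability
#' `mention_prob`, and a small fraction are non-English plants. Fully
#' reproducible from the seed.
#'
#' @param config An [synthetic_config()].
#' @return A list with `corpus` (corpus tibble) and `truth` (tibble:
#'   `article_id`, `topics` (list of positive topic ids), `key_sentences`
#'   (named list topic -> 0-based sentence indices), `country`,
#'   `country_in_title`, `dup_group`, `is_english`).
#' @export
generate_corpus <- function(config = synthetic_config()) {
  vocab <- topic_vocabularies()[seq_len(config$n_topics)]
  if (config$vocab_overlap > 0) {
    shared <- paste0("shared", seq_len(config$vocab_overlap))
    vocab <- lapply(vocab, function(v) c(v, shared))
  }
  if (any(vapply(vocab, length, integer(1)) == 0)) {
    validation_error("empty topic vocabulary")
  }
  bg <- background_vocabulary()
  gaz <- load_gazetteer()
  pool <- config$country_pool
  missing <- setdiff(pool, unique(gaz$code))
  if (length(missing) > 0) {
    validation_error("country pool code '%s' not in gazetteer", missing[1])
  }
  n_dup <- round(config$duplicate_frac * config$n_articles)
  n_base <- config$n_articles - n_dup
  stopifnot(n_base >= 1)

  with_seed(derive_seed(config$seed, "corpus"), {
    n_non_en <- rbinom(1, n_base, config$non_english_frac)
    non_en_idx <- if (n_non_en > 0) sample.int(n_base, n_non_en) else integer(0)
    arts <- vector("list", n_base)
    truths <- vector("list", n_base)
    for (i in seq_len(n_base)) {
      id <- sprintf("art%05d", i)
      n_sent <- sample(config$sentences_range[1]:config$sentences_range[2], 1)
      is_en <- !(i %in% non_en_idx)
      if (!is_en) {
        nv <- non_english_vocabulary()
        sents <- vapply(seq_len(n_sent), function(j) {
          paste0(paste(sample(nv, sample(4:7, 1), replace = TRUE), collapse = " "), ".")
        }, character(1))
        topics <- integer(0)
        keys <- list()
      } else {
        sents <- vapply(seq_len(n_sent), function(j) synth_sentence(bg), character(1))
        topics <- which(runif(config$n_topics) < config$prevalence)
        keys <- list()
        if (length(topics) > 0) {
          free <- seq_len(n_sent)
          for (t in topics) {
            n_key <- min(sample(1:2, 1), length(free))
            if (n_key == 0) break
            pos <- sort(sample(free, n_key))
            free <- setdiff(free, pos)
            for (p in pos) sents[p] <- synth_key_sentence(vocab[[t]], bg)
            keys[[as.character(t)]] <- pos - 1L
          }
          topics <- as.integer(names(keys))
        }
      }
      tags <- sample(pool, sample(1:3, 1))
      country <- tags[1]
      in_title <- runif(1) < config$mention_prob
      cname <- gaz$name[match(country, gaz$code)]
      title <- if (in_title && is_en) {
        sprintf("%s %s %s report %d", cname,
                paste(sample(bg, 2, replace = TRUE), collapse = " "),
                "health", i)
      } else {
        sprintf("%s %s notes %d",
                paste(sample(bg, 2, replace = TRUE), collapse = " "),
                "weekly", i)
      }
      if (!in_title && is_en) {
        # body entities steer the embedding fallback toward the true country;
        # appended so it never displaces a planted key sentence
        sents <- c(sents, sprintf("Responders in %s said the %s continued.",
                                  cname, sample(bg, 1)))
      }
      arts[[i]] <- tibble::tibble(
        article_id = id, title = title,
        body = paste(sents, collapse = " "),
        source = sprintf("outlet%02d", sample.int(40, 1)),
        published_at = as.Date("2021-01-01") + sample.int(500, 1),
        country_tags = list(tags),
        language = "en"
      )
      truths[[i]] <- tibble::tibble(
        article_id = id, topics = list(as.integer(topics)),
        key_sentences = list(keys), country = country,
        country_in_title = in_title && is_en,
        dup_group = id, is_english = is_en
      )
    }
    corpus <- dplyr::bind_rows(arts)
    truth <- dplyr::bind_rows(truths)
    if (n_dup > 0) {
      src <- sample.int(n_base, n_dup, replace = TRUE)
      dup_arts <- vector("list", n_dup)
      dup_truths <- vector("list", n_dup)
      for (j in seq_len(n_dup)) {
        o <- src[j]
        id <- sprintf("dup%05d", j)
        dup_arts[[j]] <- corpus[o, , drop = FALSE] |>
          dplyr::mutate(article_id = id,
                        published_at = .data$published_at + sample.int(30, 1))
        dup_truths[[j]] <- truth[o, , drop = FALSE] |>
          dplyr::mutate(article_id = id)
      }
      corpus <- dplyr::bind_rows(corpus, dplyr::bind_rows(dup_arts))
      truth <- dplyr::bind_rows(truth, dplyr::bind_rows(dup_truths))
    }
    list(corpus = corpus, truth = truth)
  })
}

#' Simulate multi-rater sentence annotations
#'
#' For every article with planted key sentences, each of `r` raters either
#' copies the ground-truth key-sentence selection (probability `alpha`) or
#' selects 1–3 sentences uniformly at random. `alpha = 1` gives perfect
#' agreement; `alpha = 0` gives chance-level agreement.
#'
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @param sentences Sentence index for the corpus.
#' @param r Number of raters (default 3).
#' @param alpha Agreement level in \eqn{[0, 1]}.
#' @param seed Integer seed.
#' @return A list with `ratings` (items-by-2 count matrix over
#'   (article, sentence) items; categories selected/not_selected) and
#'   `selections` (tibble `article_id`, `rater`, `selected_indices`).
#' @export
generate_annotations <- function(truth, sentences, r = 3L, alpha = 0.8, seed = 1L) {
  stopifnot(r >= 2)
  assert_fraction(alpha, "alpha")
  rated <- truth[vapply(truth$key_sentences, length, integer(1)) > 0, , drop = FALSE]
  with_seed(derive_seed(seed, "annotations"), {
    sel_rows <- list()
    items <- list()
    for (i in seq_len(nrow(rated))) {
      id <- rated$article_id[i]
      n_sent <- sum(sentences$article_id == id)
      gt_sel <- sort(unique(unlist(rated$key_sentences[[i]])))
      gt_sel <- utils::head(gt_sel, 3L)
      counts <- integer(n_sent)
      for (rater in seq_len(r)) {
        sel <- if (runif(1) < alpha) {
          gt_sel
        } else {
          sort(sample(0:(n_sent - 1L), min(sample(1:3, 1), n_sent)))
        }
        counts[sel + 1L] <- counts[sel + 1L] + 1L
        sel_rows[[length(sel_rows) + 1L]] <-
          tibble::tibble(article_id = id, rater = rater,
                         selected_indices = list(sel))
      }
      items[[length(items) + 1L]] <-
        cbind(selected = counts, not_selected = r - counts)
    }
    ratings <- do.call(rbind, items)
    list(ratings = ratings, selections = dplyr::bind_rows(sel_rows))
  })
}

#' Generate abstractive-style highlights with ground truth
#'
#' Builds 1–3 highlights per article by copying key sentences (for positives)
#' or random sentences (for background articles) with token dropout at the
#' configured rate, emulating a news-highlights pretraining corpus. With
#' dropout 0 the greedy oracle recovers the source indices exactly.
#'
#' @param corpus Corpus tibble.
#' @param sentences Sentence index for the corpus.
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @param dropout Token dropout rate in \eqn{[0, 1]}.
#' @param seed Integer seed.
#' @return A tibble `article_id`, `highlights` (list of character vectors),
#'   `source_indices` (list of 0-based sentence indices the highlights copy).
#' @export
generate_highlights <- function(corpus, sentences, truth, dropout = 0.1, seed = 1L) {
  assert_fraction(dropout, "dropout")
  with_seed(derive_seed(seed, "highlights"), {
    purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
      id <- corpus$article_id[i]
      sn <- sentences[sentences$article_id == id, , drop = FALSE]
      if (nrow(sn) == 0) {
        return(tibble::tibble(article_id = id, highlights = list(character(0)),
                              source_indices = list(integer(0))))
      }
      ti <- match(id, truth$article_id)
      keys <- sort(unique(unlist(truth$key_sentences[[ti]])))
      src <- if (length(keys) > 0) {
        utils::head(keys, 3L)
      } else {
        sort(sample(0:(nrow(sn) - 1L), min(sample(1:3, 1), nrow(sn))))
      }
      hl <- vapply(src, function(s) {
        toks <- tokenize1(sn$text[sn$sentence == s])
        keep <- runif(length(toks)) >= dropout
        if (!any(keep)) keep[sample.int(length(toks), 1)] <- TRUE
        paste(toks[keep], collapse = " ")
      }, character(1))
      tibble::tibble(article_id = id, highlights = list(hl),
                     source_indices = list(as.integer(src)))
    })
  })
}
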