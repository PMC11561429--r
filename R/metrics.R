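#' ROUGE-N F1 between a candidate and a reference text
#'
#' Clipped n-gram overlap: precision is the fraction of candidate n-grams
#' also in the reference (counts clipped to reference counts), recall the
#' converse, and the score is their harmonic mean. Tokenization: lowercase,
#' split on non-alphanumerics, no stemming or stopword removal. Returns 0
#' when either side has no n-grams.
#'
#' @param candidate,reference Character scalars.
#' @param n N-gram order, 1 or 2.
#' @return F1 on the 0–100 scale.
#' @export
#' @examples
#' rouge_n("a b c", "a x c", n = 1) # 66.67
rouge_n <- function(candidate, reference, n = 1L) {
  stopifnot(n %in% c(1L, 2L))
  ct <- ngrams(tokenize1(candidate), n)
  rt <- ngrams(tokenize1(reference), n)
  if (length(ct) == 0 || length(rt) == 0) return(0)
  ctab <- table(ct); rtab <- table(rt)
  shared <- intersect(names(ctab), names(rtab))
  overlap <- sum(pmin(ctab[shared], rtab[shared]))
  p <- overlap / length(ct)
  r <- overlap / length(rt)
  if (p + r == 0) return(0)
  100 * 2 * p * r / (p + r)
}

ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character(0))
  if (n == 1L) return(tokens)
  vapply(seq_len(length(tokens) - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = " ")
  }, character(1))
}

# longest common subsequence length via dynamic programming
lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L F1 between a candidate and a reference text
#'
#' Longest-common-subsequence F1 on tokens.
#'
#' @inheritParams rouge_n
#' @return F1 on the 0–100 scale.
#' @export
rouge_l <- function(candidate, reference) {
  ct <- tokenize1(candidate)
  rt <- tokenize1(reference)
  if (length(ct) == 0 || length(rt) == 0) return(0)
  l <- lcs_length(ct, rt)
  p <- l / length(ct); r <- l / length(rt)
  if (p + r == 0) return(0)
  100 * 2 * p * r / (p + r)
}

#' Mean of ROUGE-1, ROUGE-2 and ROUGE-L
#' @inheritParams rouge_n
#' @return Mean F1 on the 0–100 scale.
#' @export
rouge_mean <- function(candidate, reference) {
  mean(c(rouge_n(candidate, reference, 1L),
         rouge_n(candidate, reference, 2L),
         rouge_l(candidate, reference)))
}

# validate an items x categories count matrix with constant raters per item
check_ratings <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    validation_error("ratings table entries must be non-negative integers")
  }
  r <- unique(rowSums(table))
  if (length(r) != 1L) {
    validation_error("every item must have the same number of ratings (rows sum to a constant)")
  }
  if (r < 2) validation_error("at least 2 raters per item are required")
  if (nrow(table) < 1) validation_error("at least one item is required")
  list(table = table, r = as.integer(r))
}

# mean per-item observed agreement, shared by Fleiss kappa and Gwet AC1
observed_agreement <- function(table, r) {
  mean((rowSums(table^2) - r) / (r * (r - 1)))
}

#' Fleiss kappa for multi-rater agreement
#'
#' Chance-corrected agreement for a fixed number of raters classifying items
#' into categories: \eqn{\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)} with the
#' squared-marginal chance term \eqn{\bar P_e = \sum_q p_q^2}. 0 at chance
#' level, 100 at perfect agreement (reported on the x100 scale).
#'
#' @param table Items-by-categories matrix of rater counts; each row sums to
#'   the (constant) number of raters.
#' @return Kappa on the x100 scale (\eqn{\le 100}).
#' @export
fleiss_kappa <- function(table) {
  ck <- check_ratings(table)
  tab <- ck$table; r <- ck$r
  p_bar <- observed_agreement(tab, r)
  p_j <- colSums(tab) / (nrow(tab) * r)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps) {
    abort("Fleiss kappa undefined: all rating mass in one category (Pe = 1)",
          class = "newswatch_undefined_metric")
  }
  100 * (p_bar - p_e) / (1 - p_e)
}

#' Gwet AC1 agreement coefficient
#'
#' Alternative chance correction less sensitive to marginal imbalance:
#' \eqn{AC1 = (\bar P - P_e)/(1 - P_e)} with
#' \eqn{P_e = \frac{1}{K-1}\sum_q \hat\pi_q (1-\hat\pi_q)}, where
#' \eqn{\hat\pi_q} is the mean proportion of ratings in category \eqn{q}.
#'
#' @inheritParams fleiss_kappa
#' @return AC1 on the x100 scale (\eqn{\le 100}).
#' @seealso [chance_agreement()] for the \eqn{P_e} term alone.
#' @export
gwet_ac1 <- function(table) {
  ck <- check_ratings(table)
  tab <- ck$table; r <- ck$r
  p_bar <- observed_agreement(tab, r)
  p_e <- chance_agreement(table) / 100
  if (1 - p_e < .Machine$double.eps) {
    abort("Gwet AC1 undefined: chance agreement is 1",
          class = "newswatch_undefined_metric")
  }
  100 * (p_bar - p_e) / (1 - p_e)
}

#' Gwet chance-agreement term
#'
#' @inheritParams fleiss_kappa
#' @return \eqn{P_e} on the x100 scale.
#' @export
chance_agreement <- function(table) {
  ck <- check_ratings(table)
  tab <- ck$table; r <- ck$r
  k <- ncol(tab)
  if (k < 2) validation_error("at least 2 categories are required")
  pi_q <- colMeans(tab / r)
  100 * sum(pi_q * (1 - pi_q)) / (k - 1)
}

#' ROC-AUC of scores against binary labels
#'
#' Computed with the rank statistic (Mann–Whitney), midranks for ties —
#' equivalent to the probability that a random positive outranks a random
#' negative, counting ties as 1/2.
#'
#' @param score Numeric scores (higher = more positive).
#' @param label Binary labels (0/1 or logical), same length.
#' @return AUC in \eqn{[0, 1]}. Reports in this package surface it x100.
#' @export
roc_auc <- function(score, label) {
  label <- as.integer(label)
  stopifnot(length(score) == length(label), length(score) >= 1)
  n_pos <- sum(label == 1L); n_neg <- sum(label == 0L)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC-AUC undefined: only one class present",
          class = "newswatch_undefined_metric")
  }
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' PR-AUC (average precision) of scores against binary labels
#'
#' Average precision with step interpolation: the mean, over positives in
#' score-descending order, of precision at each positive's rank. Ties are
#' broken by stable original order.
#'
#' @inheritParams roc_auc
#' @return Average precision in \eqn{[0, 1]}.
#' @export
pr_auc <- function(score, label) {
  label <- as.integer(label)
  stopifnot(length(score) == length(label))
  if (sum(label == 1L) == 0 || sum(label == 0L) == 0) {
    abort("PR-AUC undefined: only one class present",
          class = "newswatch_undefined_metric")
  }
  ord <- order(-score, seq_along(score))
  y <- label[ord]
  cum_pos <- cumsum(y)
  prec <- cum_pos / seq_along(y)
  sum(prec[y == 1L]) / sum(y)
}

#' Precision and recall within the top-m ranked items
#'
#' With `m = k * N` (N the rules-positive count for a topic), these are the
#' ranked-retrieval diagnostics used to judge how a classifier orders the
#' rules positives. Ties are broken by stable original order.
#'
#' @inheritParams roc_auc
#' @param m Cutoff rank, `1 <= m <= length(score)`.
#' @return Fraction in \eqn{[0, 1]}; reports surface it x100.
#' @export
precision_at <- function(score, label, m) {
  topm_positives(score, label, m)$n_hit / m
}

#' @rdname precision_at
#' @export
recall_at <- function(score, label, m) {
  tp <- topm_positives(score, label, m)
  tp$n_hit / tp$n_pos
}

topm_positives <- function(score, label, m) {
  label <- as.integer(label)
  stopifnot(length(score) == length(label))
  m <- as.integer(m)
  if (is.na(m) || m < 1L || m > length(score)) {
    validation_error("m must be between 1 and %d", length(score))
  }
  n_pos <- sum(label == 1L)
  if (n_pos == 0) validation_error("no positives: recall/precision@m undefined")
  ord <- order(-score, seq_along(score))
  list(n_hit = sum(label[ord][seq_len(m)] == 1L), n_pos = n_pos)
}
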