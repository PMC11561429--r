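#' Published large-scale deployment benchmarks
#'
#' Per-topic results reported for the original multi-million-article EIOS
#' deployment of this surveillance design: rule-based positive counts and
#' rates with human relevancy checks, classifier ranking metrics, and
#' extractive-summarization ROUGE means under each supervision mix. These
#' depend on the non-public EIOS corpus and private annotations and are
#' *not* reproducible at desk scale; they ship as plain-text CSVs for report
#' formatting examples and for arithmetic cross-checks (recomputing summary
#' rows from the per-topic values).
#'
#' @return A named list of tibbles: `rules` (topic_id, n_positive, rate_pct,
#'   relevant_n, relevant_sample), `classifier` (per-topic ROC-AUC, PR-AUC,
#'   precision/recall at 2N and 10N), `summarizer` (per-topic mean ROUGE per
#'   supervision mix) and `label_counts` (key label bookkeeping counts).
#' @export
reference_benchmarks <- function() {
  dir <- system.file("extdata", "reference_benchmarks", package = "newswatch")
  list(
    rules = readr::read_csv(file.path(dir, "rules_table.csv"),
                            show_col_types = FALSE, progress = FALSE),
    classifier = readr::read_csv(file.path(dir, "classifier_table.csv"),
                                 show_col_types = FALSE, progress = FALSE),
    summarizer = readr::read_csv(file.path(dir, "summarizer_table.csv"),
                                 show_col_types = FALSE, progress = FALSE),
    label_counts = readr::read_csv(file.path(dir, "label_counts.csv"),
                                   show_col_types = FALSE, progress = FALSE)
  )
}
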