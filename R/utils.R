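#' Tokenize text for matching and metrics
#'
#' Lowercases and splits on runs of non-alphanumeric characters. This is the
#' single tokenization used by the rule engine, the ROUGE metrics, the greedy
#' oracle, and the hashing encoders, so that a keyword phrase matches exactly
#' when its token sequence occurs contiguously in the text.
#'
#' @param text Character vector.
#' @return A list of character vectors, one per element of `text`. Empty
#'   strings tokenize to `character(0)`.
#' @export
#' @examples
#' nw_tokenize("Nurses strike in Nairobi!")
nw_tokenize <- function(text) {
  text <- tolower(as.character(text))
  out <- strsplit(text, "[^a-z0-9]+")
  lapply(out, function(x) x[nzchar(x)])
}

# scalar variant, returns character vector
tokenize1 <- function(text) nw_tokenize(text)[[1]]

#' Deterministic string hash
#'
#' Polynomial rolling hash over UTF-8 bytes (FNV-style), stable across
#' platforms and R sessions. Used by the feature-hashing encoders; not
#' cryptographic.
#'
#' @param x Character vector.
#' @param seed Integer mixed into the hash so that differently seeded encoders
#'   give independent projections.
#' @return Integer vector of non-negative hashes (< 2^31).
#' @keywords internal
nw_hash <- function(x, seed = 0L) {
  vapply(x, function(s) {
    bytes <- utf8ToInt(enc2utf8(s))
    h <- (2166136261 + as.double(seed) * 2654435761) %% 2147483647
    for (b in bytes) {
      h <- (h * 16777619 + b) %% 2147483647
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# stop with a classed validation error
validation_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "newswatch_validation_error")
}

# derive a child seed from a global seed and a stage label, kept below 2^31
derive_seed <- function(seed, label) {
  as.integer((as.double(seed) * 48271 + nw_hash(label)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a fixed seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# check a scalar probability/fraction
assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    validation_error("`%s` must be a single number in [0, 1]", name)
  }
  invisible(x)
}
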