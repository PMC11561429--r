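#' Seeded feature-hashing text encoder
#'
#' Returns a deterministic encoder function mapping text to a fixed-dimension
#' real vector: each token is hashed to one coordinate with a hashed sign
#' (signed feature hashing), counts are accumulated and the result is
#' L2-normalized. The encoder honours the contract shared by every model in
#' the package — `function(text) -> numeric(dim)`, deterministic for fixed
#' text — so a pretrained contextual sentence/document encoder can be dropped
#' in for production use without touching any other code.
#'
#' @param dim Output dimension (default 256).
#' @param seed Integer seed mixed into the hash; differently seeded encoders
#'   give independent projections.
#' @return A function of class `nw_encoder` with a `dim` attribute.
#' @export
#' @examples
#' enc <- hashing_encoder(dim = 16, seed = 1)
#' v <- enc("nurses on strike")
#' length(v)
hashing_encoder <- function(dim = 256L, seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2)
  cache <- new.env(parent = emptyenv())
  token_slot <- function(tok) {
    hit <- cache[[tok]]
    if (!is.null(hit)) return(hit)
    h1 <- nw_hash(tok, seed)
    h2 <- nw_hash(tok, seed + 104729L)
    slot <- c(idx = (h1 %% dim) + 1L, sign = if (h2 %% 2L == 0L) 1L else -1L)
    assign(tok, slot, envir = cache)
    slot
  }
  f <- function(text) {
    v <- numeric(dim)
    toks <- tokenize1(text)
    for (tok in toks) {
      s <- token_slot(tok)
      v[s[["idx"]]] <- v[s[["idx"]]] + s[["sign"]]
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    v
  }
  attr(f, "nw_dim") <- dim
  attr(f, "nw_seed") <- as.integer(seed)
  class(f) <- c("nw_encoder", "function")
  f
}

#' Dimension of an encoder's output
#' @param encoder An encoder function.
#' @return Integer dimension (probed with a call if not recorded).
#' @export
encoder_dim <- function(encoder) {
  d <- attr(encoder, "nw_dim")
  if (is.null(d)) d <- length(encoder("probe"))
  as.integer(d)
}

#' Encode a document as title + body under a hard token cap
#'
#' Concatenates the title and body token streams with the title first and
#' truncates the *body tail* so that at most `max_tokens` tokens enter the
#' encoder (mirroring a transformer's fixed input window).
#'
#' @param encoder An encoder function (e.g. [hashing_encoder()]).
#' @param title,body Character scalars.
#' @param max_tokens Hard cap on total tokens (default 512).
#' @return Numeric vector of length `encoder_dim(encoder)`.
#' @export
encode_document <- function(encoder, title, body, max_tokens = 512L) {
  toks <- c(tokenize1(title), tokenize1(body))
  if (length(toks) > max_tokens) toks <- toks[seq_len(max_tokens)]
  encoder(paste(toks, collapse = " "))
}

#' Encode many texts into a feature matrix
#'
#' @param encoder An encoder function.
#' @param texts Character vector.
#' @return Numeric matrix, `length(texts)` rows by `encoder_dim(encoder)`
#'   columns.
#' @export
encode_texts <- function(encoder, texts) {
  d <- encoder_dim(encoder)
  out <- matrix(0, nrow = length(texts), ncol = d)
  for (i in seq_along(texts)) out[i, ] <- encoder(texts[[i]])
  out
}

# feature matrix for a corpus under the title+body document convention
encode_corpus <- function(encoder, corpus, max_tokens = 512L) {
  d <- encoder_dim(encoder)
  out <- matrix(0, nrow = nrow(corpus), ncol = d)
  for (i in seq_len(nrow(corpus))) {
    out[i, ] <- encode_document(encoder, corpus$title[i], corpus$body[i], max_tokens)
  }
  rownames(out) <- corpus$article_id
  out
}
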