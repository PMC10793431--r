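#' Tokenize a term for indexing and retrieval
#'
#' Lowercases, splits on any run of non-alphanumeric characters, and drops
#' empty tokens. No stemming and no stopword removal, so retrieval behaves
#' like a plain keyword index. Hyphen handling is a consequence of the split:
#' `tokenize_term(strip_hyphens(x))` equals `tokenize_term(x)`.
#'
#' @param term A character vector.
#' @return For a single term, a character vector of tokens; for longer input,
#'   a list of token vectors.
#' @export
#' @examples
#' tokenize_term("Kidney - Abnormal")  # "kidney" "abnormal"
tokenize_term <- function(term) {
  toks <- strsplit(tolower(term), "[^a-z0-9]+")
  toks <- lapply(toks, function(t) t[nzchar(t)])
  if (length(toks) == 1L) toks[[1L]] else toks
}

#' Build a BM25 term index over a vocabulary
#'
#' Indexes every (name, concept) and (synonym, concept) pair as its own
#' entry, so synonyms compete as separate retrieval candidates. Stores an
#' inverted postings map, per-entry token lists, document frequencies and
#' average entry length — everything Okapi BM25 scoring requires.
#'
#' @param vocab A non-empty `hpo_vocabulary`.
#' @param k1 BM25 term-frequency saturation parameter (default 1.2).
#' @param b BM25 length-normalization parameter (default 0.75).
#' @return An object of class `bm25_index`.
#' @export
build_index <- function(vocab, k1 = 1.2, b = 0.75) {
  stopifnot(inherits(vocab, "hpo_vocabulary"))
  if (length(vocab) == 0L) stop("vocabulary is empty")
  terms <- unlist(lapply(vocab$concepts, function(co) c(co$name, co$synonyms)),
                  use.names = FALSE)
  ids <- unlist(lapply(vocab$concepts, function(co) {
    rep.int(co$id, 1L + length(co$synonyms))
  }), use.names = FALSE)
  rebuild_index(terms, ids, k1 = k1, b = b)
}

#' @export
print.bm25_index <- function(x, ...) {
  cat(sprintf("<bm25_index> %d entries, %d tokens, k1=%.2f b=%.2f\n",
              x$N, length(x$df), x$k1, x$b))
  invisible(x)
}

bm25_idf <- function(index, token) {
  df <- index$df[token]
  df[is.na(df)] <- 0L
  # Non-negative Lucene-style IDF; common tokens never score below zero.
  log(1 + (index$N - df + 0.5) / (df + 0.5))
}

#' Okapi BM25 score of one indexed entry against query tokens
#'
#' `sum over query tokens t of IDF(t) * tf * (k1 + 1) / (tf + k1 * (1 - b +
#' b * len / avglen))` with `IDF(t) = ln(1 + (N - df + 0.5) / (df + 0.5))`.
#' Tokens absent from the entry contribute zero; scores are non-negative.
#'
#' @param index A `bm25_index`.
#' @param query_tokens Character vector of query tokens (duplicates are
#'   collapsed).
#' @param entry Integer entry index into `index$entries`.
#' @return A non-negative numeric score.
#' @export
bm25_score <- function(index, query_tokens, entry) {
  stopifnot(inherits(index, "bm25_index"),
            entry >= 1L, entry <= index$N)
  query_tokens <- unique(query_tokens)
  if (length(query_tokens) == 0L) return(0)
  toks <- index$tokens[[entry]]
  len <- index$lens[[entry]]
  norm <- index$k1 * (1 - index$b + index$b * len / index$avg_len)
  s <- 0
  for (t in query_tokens) {
    tf <- sum(toks == t)
    if (tf == 0) next
    s <- s + bm25_idf(index, t) * tf * (index$k1 + 1) / (tf + norm)
  }
  unname(s)
}

bm25_candidates <- function(index, query_tokens, mode) {
  hits <- lapply(query_tokens, function(t) index$postings[[t]] %||% integer())
  if (mode == "AND") {
    out <- hits[[1L]]
    for (h in hits[-1L]) out <- intersect(out, h)
    sort(out)
  } else {
    sort(unique(unlist(hits, use.names = FALSE)))
  }
}

#' Normalize a query term to a concept ID with BM25 retrieval
#'
#' Tokenizes the query, filters entries to those containing all query tokens
#' (`AND`) or at least one (`OR`), scores candidates with [bm25_score()], and
#' returns the concept ID of the top-1 entry. Ties are broken by the
#' lexicographically smallest concept ID for determinism. Returns
#' `NA_character_` when the candidate set is empty or the query has no
#' tokens.
#'
#' @param index A `bm25_index`.
#' @param query Query term string.
#' @param mode `"OR"` (at least one token matched) or `"AND"` (all tokens
#'   required). AND candidates are always a subset of OR candidates, which
#'   is why a single mistyped token makes AND fail while OR can still
#'   succeed through the unaltered tokens.
#' @return A concept ID string, or `NA_character_`.
#' @export
normalize_term <- function(index, query, mode = c("OR", "AND")) {
  stopifnot(inherits(index, "bm25_index"), is_string(query))
  mode <- match.arg(mode)
  q <- unique(tokenize_term(query))
  if (length(q) == 0L) return(NA_character_)
  cand <- bm25_candidates(index, q, mode)
  if (length(cand) == 0L) return(NA_character_)
  scores <- vapply(cand, function(e) bm25_score(index, q, e), numeric(1))
  best <- cand[scores == max(scores)]
  if (length(best) > 1L) {
    ids <- index$entries$concept_id[best]
    return(min(ids))
  }
  index$entries$concept_id[best]
}

#' Wrap a BM25 index as a normalizer function
#'
#' @param index A `bm25_index`.
#' @param mode Retrieval mode, `"OR"` or `"AND"`.
#' @return A function `term -> concept ID or NA`, the interface the
#'   evaluation harness expects.
#' @export
bm25_normalizer <- function(index, mode = c("OR", "AND")) {
  mode <- match.arg(mode)
  force(index)
  function(term) normalize_term(index, term, mode)
}

#' Persist / restore a BM25 index as JSON
#'
#' The on-disk format (version 1) stores the entry table and the BM25
#' parameters; postings and statistics are rebuilt on load, so the file stays
#' small and plain-text.
#'
#' @param index A `bm25_index`.
#' @param path File path.
#' @return `save_index()` returns `path` invisibly; `load_index()` returns a
#'   `bm25_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "bm25_index"))
  payload <- list(format = "phenonorm-bm25", version = index$version,
                  k1 = index$k1, b = index$b,
                  terms = index$entries$term,
                  concept_ids = index$entries$concept_id)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  payload <- jsonlite::fromJSON(path)
  if (!identical(payload$format, "phenonorm-bm25")) {
    stop("not a phenonorm BM25 index file: ", path)
  }
  rebuild_index(payload$terms, payload$concept_ids,
                k1 = payload$k1, b = payload$b)
}

rebuild_index <- function(terms, ids, k1 = 1.2, b = 0.75) {
  tokens <- lapply(terms, tokenize_term)
  lens <- lengths(tokens)
  flat <- unlist(lapply(tokens, unique), use.names = FALSE)
  df_tab <- table(flat)
  df <- as.integer(df_tab)
  names(df) <- names(df_tab)
  postings <- split(
    rep.int(seq_along(tokens), lengths(lapply(tokens, unique))),
    flat
  )
  structure(
    list(entries = data.frame(term = terms, concept_id = ids,
                              stringsAsFactors = FALSE),
         tokens = tokens, lens = lens, df = df, postings = postings,
         N = length(terms), avg_len = mean(lens), k1 = k1, b = b,
         version = 1L),
    class = "bm25_index"
  )
}
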