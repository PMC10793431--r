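# Independent brute-force BM25 oracle, written with plain loops and without
# any of the package's index machinery, for cross-checking normalize_term().

oracle_tokenize <- function(term) {
  m <- gregexpr("[a-z0-9]+", tolower(term))[[1]]
  if (m[1] == -1) return(character())
  regmatches(tolower(term), gregexpr("[a-z0-9]+", tolower(term)))[[1]]
}

# terms/ids: parallel vectors of every indexed surface and its concept ID.
oracle_normalize <- function(terms, ids, query, mode, k1 = 1.2, b = 0.75) {
  toks <- lapply(terms, oracle_tokenize)
  N <- length(terms)
  avg <- mean(vapply(toks, length, integer(1)))
  q <- unique(oracle_tokenize(query))
  if (length(q) == 0) return(NA_character_)

  contains <- function(entry_toks, t) t %in% entry_toks
  cand <- integer()
  for (e in seq_len(N)) {
    hits <- vapply(q, contains, logical(1), entry_toks = toks[[e]])
    keep <- if (mode == "AND") all(hits) else any(hits)
    if (keep) cand <- c(cand, e)
  }
  if (length(cand) == 0) return(NA_character_)

  df <- function(t) {
    n <- 0
    for (e in seq_len(N)) if (t %in% toks[[e]]) n <- n + 1
    n
  }
  score <- numeric(length(cand))
  for (i in seq_along(cand)) {
    e <- cand[i]
    len <- length(toks[[e]])
    s <- 0
    for (t in q) {
      tf <- sum(toks[[e]] == t)
      if (tf == 0) next
      idf <- log(1 + (N - df(t) + 0.5) / (df(t) + 0.5))
      s <- s + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len / avg))
    }
    score[i] <- s
  }
  best <- cand[score == max(score)]
  sort(ids[best])[1]
}

# All (surface, id) entries of a vocabulary, in index order.
vocab_entries <- function(vocab) {
  terms <- unlist(lapply(vocab$concepts, function(co) c(co$name, co$synonyms)),
                  use.names = FALSE)
  ids <- unlist(lapply(vocab$concepts,
                       function(co) rep(co$id, 1 + length(co$synonyms))),
                use.names = FALSE)
  list(terms = terms, ids = ids)
}

hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) return(NA_integer_)
  sum(ca != cb)
}
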