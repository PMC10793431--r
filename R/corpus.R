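#' Sentence template pieces
#'
#' All training sentences follow one template: the term, then the identifier,
#' joined by a fixed connective. Sentences are rendered without a trailing
#' period so the identifier is the final token span and the evaluation prompt
#' is the sentence truncated immediately after `"HPO ID "`.
#'
#' @name sentence_template
#' @keywords internal
NULL

TEMPLATE_HEAD <- "The Human Phenotype Ontology term "
TEMPLATE_SEP <- " is identified by the HPO ID "

#' Default prompt templates
#'
#' `hpo_prompt_template()` is the training-sentence prefix with a `{term}`
#' placeholder; `alt_prompt_template()` is a structurally different prompt
#' used to probe prompt brittleness.
#'
#' @return A template string containing `{term}`.
#' @export
hpo_prompt_template <- function() {
  paste0(TEMPLATE_HEAD, "{term}", TEMPLATE_SEP)
}

#' @rdname hpo_prompt_template
#' @export
alt_prompt_template <- function() {
  "HPO ID of {term} is "
}

#' Render one training sentence
#'
#' @param term Non-empty surface term.
#' @param concept_id Identifier matching the `HP:` + 7-digit pattern.
#' @param origin One of `"NAME"`, `"SYNONYM"`, `"TYPO"`.
#' @return A one-row data frame with columns `text`, `term`, `concept_id`,
#'   `origin`.
#' @export
#' @examples
#' render_sentence("Hearing impairment", "HP:0000365")$text
render_sentence <- function(term, concept_id, origin = "NAME") {
  if (!is_string(term) || !nzchar(term)) stop("term must be non-empty")
  if (!is_string(concept_id) || !grepl(HP_ID_REGEX, concept_id)) {
    stop("concept_id must match 'HP:' + 7 digits")
  }
  origin <- match.arg(origin, c("NAME", "SYNONYM", "TYPO"))
  data.frame(
    text = paste0(TEMPLATE_HEAD, term, TEMPLATE_SEP, concept_id),
    term = term, concept_id = concept_id, origin = origin,
    stringsAsFactors = FALSE
  )
}

#' Invert a rendered sentence
#'
#' @param text A sentence rendered by [render_sentence()].
#' @return A list with `term` and `concept_id`.
#' @export
parse_sentence <- function(text) {
  stopifnot(is_string(text))
  if (!startsWith(text, TEMPLATE_HEAD) || !grepl(TEMPLATE_SEP, text, fixed = TRUE)) {
    stop("sentence does not follow the template: ", text)
  }
  rest <- substring(text, nchar(TEMPLATE_HEAD) + 1L)
  idx <- regexpr(TEMPLATE_SEP, rest, fixed = TRUE)
  term <- substring(rest, 1L, idx - 1L)
  id <- substring(rest, idx + attr(idx, "match.length"))
  if (!grepl(HP_ID_REGEX, id)) stop("sentence tail is not an HP ID: ", id)
  list(term = term, concept_id = id)
}

new_corpus <- function(sentences, variant, held_out, seed = NA_integer_) {
  stopifnot(is.data.frame(sentences),
            all(c("text", "term", "concept_id", "origin") %in% names(sentences)),
            is.data.frame(held_out),
            all(c("term", "concept_id") %in% names(held_out)))
  variant <- match.arg(variant, c("NAME", "NAME_SYN", "NAME_SYN_TYPO"))
  structure(list(sentences = sentences, variant = variant,
                 held_out = held_out, seed = seed),
            class = "hpo_corpus")
}

#' @export
print.hpo_corpus <- function(x, ...) {
  cat(sprintf("<hpo_corpus> variant=%s: %d sentences, %d held-out synonyms\n",
              x$variant, nrow(x$sentences), nrow(x$held_out)))
  invisible(x)
}

empty_held_out <- function() {
  data.frame(term = character(), concept_id = character(),
             stringsAsFactors = FALSE)
}

#' Build the NAME fine-tuning corpus
#'
#' One sentence per concept using the preferred name only. All synonyms of
#' all concepts are recorded as held out, so synonym evaluation of a
#' NAME-trained normalizer is fully out-of-corpus.
#'
#' @param vocab A non-empty `hpo_vocabulary`.
#' @return An `hpo_corpus` with `variant = "NAME"`.
#' @export
build_name_corpus <- function(vocab) {
  stopifnot(inherits(vocab, "hpo_vocabulary"))
  if (length(vocab) == 0L) stop("vocabulary is empty")
  sentences <- do.call(rbind, lapply(vocab$concepts, function(co) {
    render_sentence(co$name, co$id, "NAME")
  }))
  rownames(sentences) <- NULL
  held <- do.call(rbind, c(list(empty_held_out()), lapply(vocab$concepts, function(co) {
    if (length(co$synonyms) == 0L) return(NULL)
    data.frame(term = co$synonyms, concept_id = co$id, stringsAsFactors = FALSE)
  })))
  rownames(held) <- NULL
  new_corpus(sentences, "NAME", held)
}

#' Build the NAME+SYN corpus with a half-synonym hold-out split
#'
#' Every concept contributes its NAME sentence plus sentences for a seeded
#' uniform random sample of `floor(n_syn / 2)` of its synonyms; the remaining
#' `ceiling(n_syn / 2)` synonyms are held out for evaluation. A concept with
#' six synonyms therefore trains on three and holds out three. Per concept
#' the training and held-out synonym sets are disjoint and together exhaust
#' the synonym list.
#'
#' @param vocab A non-empty `hpo_vocabulary`.
#' @param seed Integer seed controlling which synonyms are sampled.
#' @return An `hpo_corpus` with `variant = "NAME_SYN"`.
#' @export
build_name_syn_corpus <- function(vocab, seed = 1) {
  stopifnot(inherits(vocab, "hpo_vocabulary"))
  if (length(vocab) == 0L) stop("vocabulary is empty")
  with_seed(seed, {
    parts <- lapply(vocab$concepts, function(co) {
      n <- length(co$synonyms)
      k <- n %/% 2L
      train_idx <- if (k > 0L) sort(sample.int(n, k)) else integer()
      train_syn <- co$synonyms[train_idx]
      held_syn <- co$synonyms[setdiff(seq_len(n), train_idx)]
      sent <- rbind(
        render_sentence(co$name, co$id, "NAME"),
        if (length(train_syn)) {
          do.call(rbind, lapply(train_syn, render_sentence,
                                concept_id = co$id, origin = "SYNONYM"))
        }
      )
      held <- if (length(held_syn)) {
        data.frame(term = held_syn, concept_id = co$id, stringsAsFactors = FALSE)
      } else {
        empty_held_out()
      }
      list(sent = sent, held = held)
    })
    sentences <- do.call(rbind, lapply(parts, `[[`, "sent"))
    held <- do.call(rbind, lapply(parts, `[[`, "held"))
    rownames(sentences) <- rownames(held) <- NULL
    new_corpus(sentences, "NAME_SYN", held, seed = as.integer(seed))
  })
}

#' Build a typo-augmented corpus
#'
#' Emits one sentence per input sentence whose term is replaced by a simple
#' single-character keyboard typo of the original term (same concept ID,
#' origin `TYPO`). Intended for additional fine-tuning epochs that expose a
#' model to misspelled surfaces. The held-out list of the source corpus is
#' carried over unchanged.
#'
#' @param corpus An `hpo_corpus` with variant `NAME` or `NAME_SYN`.
#' @param seed Integer seed; output is deterministic per seed.
#' @param layout Keyboard adjacency table.
#' @return An `hpo_corpus` with `variant = "NAME_SYN_TYPO"`.
#' @export
build_typo_corpus <- function(corpus, seed = 1, layout = qwerty_layout()) {
  stopifnot(inherits(corpus, "hpo_corpus"))
  if (!corpus$variant %in% c("NAME", "NAME_SYN")) {
    stop("typo augmentation expects a NAME or NAME_SYN corpus")
  }
  with_seed(seed, {
    sentences <- do.call(rbind, lapply(seq_len(nrow(corpus$sentences)), function(i) {
      term <- corpus$sentences$term[i]
      render_sentence(simple_typo(term, layout), corpus$sentences$concept_id[i],
                      "TYPO")
    }))
    rownames(sentences) <- NULL
    new_corpus(sentences, "NAME_SYN_TYPO", corpus$held_out,
               seed = as.integer(seed))
  })
}

#' Write / read a corpus as JSONL
#'
#' One JSON object per line with fields `text`, `term`, `concept_id`,
#' `origin`. `write_corpus_text()` writes the bare sentences, one per line.
#'
#' @param corpus An `hpo_corpus`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "hpo_corpus"))
  lines <- vapply(seq_len(nrow(corpus$sentences)), function(i) {
    jsonlite::toJSON(as.list(corpus$sentences[i, , drop = FALSE]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @param variant Corpus variant to stamp on the re-read corpus.
#' @export
read_corpus_jsonl <- function(path, variant = "NAME") {
  lines <- readLines(path, warn = FALSE)
  sentences <- do.call(rbind, lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  }))
  new_corpus(sentences, variant, empty_held_out())
}

#' @rdname write_corpus_jsonl
#' @export
write_corpus_text <- function(corpus, path) {
  writeLines(corpus$sentences$text, path)
  invisible(path)
}

#' Write held-out synonyms as TSV
#'
#' Columns `term`, `concept_id`.
#'
#' @param corpus An `hpo_corpus`.
#' @param path Output path.
#' @return Invisibly, the held-out data frame.
#' @export
write_held_out_tsv <- function(corpus, path) {
  utils::write.table(corpus$held_out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(corpus$held_out)
}
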