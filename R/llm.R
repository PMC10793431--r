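#' Split a corpus into prompt/completion training records
#'
#' Each template sentence is split immediately after `"HPO ID "`: the prompt
#' is the prefix up to and including that marker, the completion is the
#' identifier that follows. `prompt + completion` reconstructs every sentence
#' byte-for-byte, which is the natural shape for next-token-prediction
#' fine-tuning of an autoregressive model.
#'
#' @param corpus An `hpo_corpus`.
#' @return A data frame with columns `text`, `prompt`, `completion`.
#' @export
#' @examples
#' v <- generate_fixture(3, c(0, 0), seed = 1)
#' make_records(build_name_corpus(v))
make_records <- function(corpus) {
  stopifnot(inherits(corpus, "hpo_corpus"))
  texts <- corpus$sentences$text
  if (length(texts) == 0L) {
    return(data.frame(text = character(), prompt = character(),
                      completion = character(), stringsAsFactors = FALSE))
  }
  marker <- "HPO ID "
  pos <- regexpr(marker, texts, fixed = TRUE)
  bad <- which(pos < 0L)
  if (length(bad)) {
    stop("sentence does not follow the template: ", texts[bad[1L]])
  }
  cut <- pos + attr(pos, "match.length")
  prompt <- substring(texts, 1L, cut - 1L)
  completion <- substring(texts, cut)
  bad <- which(!grepl(HP_ID_REGEX, completion))
  if (length(bad)) {
    stop("sentence completion is not an HP ID: ", texts[bad[1L]])
  }
  data.frame(text = texts, prompt = prompt, completion = completion,
             stringsAsFactors = FALSE)
}

#' Extract the first HPO identifier from generated text
#'
#' Finds the first substring matching `HP:` + 7 digits (case-insensitive on
#' the `HP` prefix, normalized to upper case). Generated continuations —
#' including hallucinated identifiers, which follow the same surface format —
#' are reduced to a well-formed ID or `NA`. Idempotent on its own output and
#' never returns a malformed ID.
#'
#' @param completion Character vector of generated text.
#' @return Character vector of IDs (`NA_character_` where absent).
#' @export
#' @examples
#' extract_hpo_id("the ID is HP:0012824 which corresponds to Severity")
extract_hpo_id <- function(completion) {
  m <- regexpr("[Hh][Pp]:[0-9]{7}", completion)
  out <- rep(NA_character_, length(completion))
  hit <- m > 0L
  out[hit] <- toupper(regmatches(completion, m))
  out
}

#' Fine-tuning configuration
#'
#' Carries the hyperparameters of the fine-tuning recipe: 100 epochs on the
#' clean corpus, 30 additional epochs on the typo-augmented corpus, LoRA rank
#' 32, batch size 128. The LoRA fields are configuration for adapter-based
#' training of large base models; the built-in character-level model trains
#' all of its (few) weights and records the LoRA fields untouched.
#'
#' @param epochs Number of training epochs (default 100).
#' @param typo_extra_epochs Additional epochs on a typo-augmented corpus
#'   (default 30).
#' @param lora_rank Low-rank adapter rank `r` (default 32).
#' @param batch_size Minibatch size (default 128).
#' @param seed Integer seed for shuffling and initialization.
#' @param base_model Opaque identifier of the base model.
#' @param learning_rate Optimizer step size (default 0.005, Adam).
#' @return An object of class `finetune_config`.
#' @export
finetune_config <- function(epochs = 100L, typo_extra_epochs = 30L,
                            lora_rank = 32L, batch_size = 128L, seed = 1L,
                            base_model = "char-mlp",
                            learning_rate = 0.005) {
  stopifnot(epochs >= 0, lora_rank >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 typo_extra_epochs = as.integer(typo_extra_epochs),
                 lora_rank = as.integer(lora_rank),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 base_model = base_model,
                 learning_rate = learning_rate),
            class = "finetune_config")
}

#' Greedy completion generic
#'
#' Any completion model implements `complete(model, prompt)`: given a prompt
#' string it returns a bounded-length greedy continuation. Greedy decoding
#' makes evaluation deterministic.
#'
#' @param model A completion model.
#' @param prompt Prompt string.
#' @param max_chars Maximum continuation length (an HP ID plus slack).
#' @param ... Method-specific arguments.
#' @return The generated continuation string.
#' @export
complete <- function(model, prompt, max_chars = 16L, ...) {
  UseMethod("complete")
}

#' Fine-tuning generic
#'
#' Trains a completion model on prompt/completion records under a
#' [finetune_config()]. Models that do not support training signal a
#' capability error. With `epochs = 0` the model is returned unchanged with
#' an empty loss trace.
#'
#' @param model A completion model.
#' @param records Data frame from [make_records()].
#' @param config A [finetune_config()].
#' @param ... Method-specific arguments.
#' @return A list with elements `model` (updated model) and `loss`
#'   (per-epoch mean negative log-likelihood).
#' @export
finetune <- function(model, records, config = finetune_config(), ...) {
  UseMethod("finetune")
}

#' @export
finetune.default <- function(model, records, config = finetune_config(), ...) {
  stop("model of class ", paste(class(model), collapse = "/"),
       " does not support fine-tuning")
}

#' Memorizing lookup stub model
#'
#' A completion model that memorizes an exact prompt-to-completion table and
#' returns `""` for any unseen prompt. Useful as the upper-bound stub in
#' harness tests: it is perfect on its training prompts and maximally brittle
#' to any prompt rewording.
#'
#' @param records Data frame with `prompt` and `completion` columns.
#' @return An object of classes `lookup_model`, `completion_model`.
#' @export
lookup_model <- function(records) {
  stopifnot(all(c("prompt", "completion") %in% names(records)))
  tab <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(records))) {
    assign(records$prompt[i], records$completion[i], envir = tab)
  }
  structure(list(table = tab), class = c("lookup_model", "completion_model"))
}

#' @export
complete.lookup_model <- function(model, prompt, max_chars = 16L, ...) {
  if (exists(prompt, envir = model$table, inherits = FALSE)) {
    substr(get(prompt, envir = model$table), 1L, max_chars)
  } else {
    ""
  }
}

#' Constant-output stub model
#'
#' Always returns the same text regardless of the prompt; the degenerate
#' lower-bound stub for harness tests.
#'
#' @param text The fixed continuation.
#' @return An object of classes `constant_model`, `completion_model`.
#' @export
constant_model <- function(text = "") {
  structure(list(text = text), class = c("constant_model", "completion_model"))
}

#' @export
complete.constant_model <- function(model, prompt, max_chars = 16L, ...) {
  substr(model$text, 1L, max_chars)
}

render_prompt <- function(template, term) {
  if (!grepl("{term}", template, fixed = TRUE)) {
    stop("prompt template must contain one '{term}' placeholder")
  }
  sub("{term}", term, template, fixed = TRUE)
}

#' Wrap a completion model as a normalizer
#'
#' Renders the prompt template with the query term, requests a greedy
#' completion, and extracts the first HPO identifier. The returned function
#' has the `term -> ID or NA` signature the evaluation harness uses for every
#' normalizer, so completion models and the BM25 baseline are scored through
#' the same code path.
#'
#' @param model A completion model.
#' @param prompt_template Template containing one `{term}` placeholder;
#'   defaults to the training-sentence prompt [hpo_prompt_template()].
#' @param max_chars Continuation length cap.
#' @return A function `term -> concept ID or NA`.
#' @export
completion_normalizer <- function(model,
                                  prompt_template = hpo_prompt_template(),
                                  max_chars = 16L) {
  force(model); force(prompt_template); force(max_chars)
  if (!grepl("{term}", prompt_template, fixed = TRUE)) {
    stop("prompt template must contain one '{term}' placeholder")
  }
  function(term) {
    prompt <- render_prompt(prompt_template, term)
    extract_hpo_id(complete(model, prompt, max_chars = max_chars))
  }
}

#' Write / read training records as JSONL
#'
#' One JSON object per line with fields `prompt` and `completion`.
#'
#' @param records Data frame from [make_records()].
#' @param path File path.
#' @return `write_records_jsonl()` returns `path` invisibly;
#'   `read_records_jsonl()` returns the records data frame (with `text`
#'   reconstructed).
#' @export
write_records_jsonl <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(list(prompt = records$prompt[i],
                          completion = records$completion[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_records_jsonl
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- do.call(rbind, lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  }))
  recs$text <- paste0(recs$prompt, recs$completion)
  recs[, c("text", "prompt", "completion")]
}
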