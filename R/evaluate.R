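QUERY_CATEGORIES <- c("TRAIN_NAME", "HELD_OUT_SYNONYM", "SIMPLE_TYPO",
                      "COMPLEX_TYPO", "XREF", "LAYMEN")

query_frame <- function(term = character(), gold_id = character(),
                        category = character(), source_term = character()) {
  data.frame(term = term, gold_id = gold_id, category = category,
             source_term = source_term, stringsAsFactors = FALSE)
}

#' Build the categorized evaluation query sets
#'
#' Assembles queries for up to six categories: `TRAIN_NAME` (every preferred
#' name), `HELD_OUT_SYNONYM` (synonyms withheld from training),
#' `SIMPLE_TYPO` and `COMPLEX_TYPO` (keyboard perturbations of preferred
#' names, seeded), `XREF` (cross-referenced surface terms), and `LAYMEN`
#' (colloquial paraphrases supplied as a data frame or TSV with columns
#' `term`, `gold_id`). Laymen rows whose gold ID is not in the vocabulary are
#' dropped with a warning giving the count.
#'
#' @param vocab An `hpo_vocabulary`.
#' @param held_out Data frame (`term`, `concept_id`) of held-out synonyms,
#'   e.g. `corpus$held_out`; `NULL` to skip the category.
#' @param xrefs Query data frame from [extract_xref_terms()]; `NULL` to skip.
#' @param laymen Data frame or TSV path (`term`, `gold_id`); `NULL` to skip.
#' @param layout Keyboard adjacency table for the typo categories.
#' @param seed Integer seed for the typo draws.
#' @return A data frame of query items: `term`, `gold_id`, `category`,
#'   `source_term` (the unperturbed term for typo categories, `NA`
#'   elsewhere).
#' @export
build_query_sets <- function(vocab, held_out = NULL, xrefs = NULL,
                             laymen = NULL, layout = qwerty_layout(),
                             seed = 1) {
  stopifnot(inherits(vocab, "hpo_vocabulary"))
  ids <- vocab_ids(vocab)
  nms <- vocab_names(vocab)
  parts <- list(
    query_frame(nms, ids, rep("TRAIN_NAME", length(nms)),
                rep(NA_character_, length(nms)))
  )
  if (!is.null(held_out) && nrow(held_out) > 0L) {
    parts <- c(parts, list(query_frame(
      held_out$term, held_out$concept_id,
      rep("HELD_OUT_SYNONYM", nrow(held_out)),
      rep(NA_character_, nrow(held_out))
    )))
  }
  typos <- with_seed(seed, {
    simple <- vapply(nms, function(t) simple_typo(t, layout), character(1))
    cx <- vapply(nms, function(t) complex_typo(t, layout), character(1))
    list(simple = unname(simple), complex = unname(cx))
  })
  parts <- c(parts, list(
    query_frame(typos$simple, ids, rep("SIMPLE_TYPO", length(nms)), nms),
    query_frame(typos$complex, ids, rep("COMPLEX_TYPO", length(nms)), nms)
  ))
  if (!is.null(xrefs) && nrow(xrefs) > 0L) {
    parts <- c(parts, list(query_frame(
      xrefs$term, xrefs$gold_id, rep("XREF", nrow(xrefs)),
      rep(NA_character_, nrow(xrefs))
    )))
  }
  if (!is.null(laymen)) {
    if (is_string(laymen)) {
      laymen <- utils::read.delim(laymen, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("term", "gold_id") %in% names(laymen)))
    unknown <- !(laymen$gold_id %in% ids)
    if (any(unknown)) {
      warning(sum(unknown), " laymen row(s) with unknown gold IDs dropped")
      laymen <- laymen[!unknown, , drop = FALSE]
    }
    if (nrow(laymen) > 0L) {
      parts <- c(parts, list(query_frame(
        laymen$term, laymen$gold_id, rep("LAYMEN", nrow(laymen)),
        rep(NA_character_, nrow(laymen))
      )))
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Score a normalizer over categorized queries
#'
#' Runs `normalizer(term)` for every query; a prediction is correct iff the
#' returned ID equals the gold ID exactly (string comparison on upper-cased
#' IDs). `NA` results and errors raised by the normalizer are recorded as
#' no-prediction, which counts as incorrect in the accuracy. For each wrong
#' well-formed prediction the digit-level suffix mismatch length against the
#' gold ID (how many trailing digits would have to change) is recorded as a
#' near-miss diagnostic — it never contributes partial credit.
#'
#' @param normalizer A function `term -> concept ID or NA` (see
#'   [bm25_normalizer()], [completion_normalizer()]).
#' @param queries Data frame from [build_query_sets()].
#' @param id Label for this normalizer in the report.
#' @param metadata Optional named list stored in the report.
#' @return An object of class `phenonorm_report` with elements `rows`
#'   (per-category `n_total`, `n_correct`, `n_no_prediction`, `accuracy`),
#'   `outcomes` (per-query results), and `metadata`.
#' @export
evaluate_normalizer <- function(normalizer, queries, id = "normalizer",
                                metadata = list()) {
  stopifnot(is.function(normalizer), is.data.frame(queries),
            all(c("term", "gold_id", "category") %in% names(queries)))
  n <- nrow(queries)
  pred <- character(n)
  for (i in seq_len(n)) {
    pred[i] <- tryCatch({
      p <- normalizer(queries$term[i])
      if (length(p) != 1L || is.na(p)) NA_character_ else toupper(p)
    }, error = function(e) NA_character_)
  }
  correct <- !is.na(pred) & pred == queries$gold_id
  suffix_mismatch <- rep(NA_integer_, n)
  wrong_formed <- !correct & !is.na(pred) & grepl(HP_ID_REGEX, pred)
  for (i in which(wrong_formed)) {
    suffix_mismatch[i] <- digit_suffix_mismatch(pred[i], queries$gold_id[i])
  }
  outcomes <- cbind(queries,
                    data.frame(predicted = pred, correct = correct,
                               no_prediction = is.na(pred),
                               digit_suffix_mismatch = suffix_mismatch,
                               stringsAsFactors = FALSE))
  cats <- intersect(QUERY_CATEGORIES, unique(queries$category))
  rows <- do.call(rbind, lapply(cats, function(cc) {
    sel <- queries$category == cc
    data.frame(normalizer = id, category = cc,
               n_total = sum(sel),
               n_correct = sum(correct[sel]),
               n_no_prediction = sum(is.na(pred[sel])),
               accuracy = sum(correct[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  structure(list(rows = rows, outcomes = outcomes,
                 metadata = c(list(normalizer = id), metadata)),
            class = "phenonorm_report")
}

# Number of trailing digits by which two well-formed IDs differ: 7 minus the
# length of the common digit prefix. 0 only for identical IDs.
digit_suffix_mismatch <- function(pred, gold) {
  dp <- strsplit(substring(pred, 4L), "")[[1]]
  dg <- strsplit(substring(gold, 4L), "")[[1]]
  same <- dp == dg
  first_diff <- which(!same)
  if (length(first_diff) == 0L) return(0L)
  7L - min(first_diff) + 1L
}

#' @export
print.phenonorm_report <- function(x, ...) {
  cat(render_report_text(x), sep = "\n")
  invisible(x)
}

#' Combine evaluation reports
#'
#' Stacks the rows (and outcomes) of several reports, e.g. one per
#' normalizer, into a single table mirroring a categories-by-normalizers
#' accuracy matrix.
#'
#' @param ... `phenonorm_report` objects.
#' @return A `phenonorm_report`.
#' @export
combine_reports <- function(...) {
  reports <- list(...)
  stopifnot(all(vapply(reports, inherits, logical(1), "phenonorm_report")))
  structure(
    list(rows = do.call(rbind, lapply(reports, `[[`, "rows")),
         outcomes = do.call(rbind, lapply(reports, function(r) {
           cbind(normalizer = r$metadata$normalizer, r$outcomes)
         })),
         metadata = list(combined = lapply(reports, `[[`, "metadata"))),
    class = "phenonorm_report"
  )
}

#' Probe prompt robustness of a completion model
#'
#' Evaluates the same completion model under several prompt templates; the
#' default set is the training template plus the structurally different
#' `"HPO ID of {term} is "`. A model fine-tuned on one sentence structure is
#' expected to degrade under reworded prompts.
#'
#' @param model A completion model.
#' @param queries Query data frame.
#' @param templates Character vector of templates with a `{term}`
#'   placeholder.
#' @param id Label prefix for report rows.
#' @return A `phenonorm_report` with one set of rows per template; each row
#'   block's template is carried in `metadata$templates` and in the
#'   `template` column of `rows`.
#' @export
prompt_robustness <- function(model, queries,
                              templates = c(hpo_prompt_template(),
                                            alt_prompt_template()),
                              id = "completion") {
  reports <- lapply(seq_along(templates), function(i) {
    r <- evaluate_normalizer(
      completion_normalizer(model, templates[i]),
      queries,
      id = sprintf("%s[template %d]", id, i),
      metadata = list(template = templates[i])
    )
    r$rows$template <- templates[i]
    r
  })
  out <- do.call(combine_reports, reports)
  out$metadata$templates <- templates
  out
}

render_report_text <- function(report) {
  rows <- report$rows
  pct <- sprintf("%.1f%%", 100 * rows$accuracy)
  widths <- c(norm = max(nchar(c("normalizer", rows$normalizer))),
              cat = max(nchar(c("category", rows$category))))
  fmt <- sprintf("%%-%ds  %%-%ds  %%7s  %%9s  %%9s  %%8s",
                 widths["norm"], widths["cat"])
  c(sprintf(fmt, "normalizer", "category", "n_total", "n_correct",
            "n_no_pred", "accuracy"),
    vapply(seq_len(nrow(rows)), function(i) {
      sprintf(fmt, rows$normalizer[i], rows$category[i],
              rows$n_total[i], rows$n_correct[i],
              rows$n_no_prediction[i], pct[i])
    }, character(1)))
}

#' Render an evaluation report
#'
#' `format = "tsv"` writes one row per (normalizer, category) with the
#' accuracy as a percentage rounded to one decimal (column `accuracy_pct`);
#' `format = "text"` renders an aligned table with `"45.0%"`-style cells.
#'
#' @param report A `phenonorm_report`.
#' @param path Output file, or `NULL` to return the rendering only.
#' @param format `"tsv"` or `"text"`.
#' @return Invisibly, the character vector of rendered lines.
#' @export
write_report <- function(report, path = NULL, format = c("tsv", "text")) {
  stopifnot(inherits(report, "phenonorm_report"))
  format <- match.arg(format)
  if (format == "text") {
    lines <- render_report_text(report)
  } else {
    rows <- report$rows
    out <- data.frame(normalizer = rows$normalizer, category = rows$category,
                      n_total = rows$n_total, n_correct = rows$n_correct,
                      n_no_prediction = rows$n_no_prediction,
                      accuracy_pct = sprintf("%.1f", 100 * rows$accuracy),
                      stringsAsFactors = FALSE)
    con <- textConnection("lines_out", "w", local = TRUE)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    lines <- lines_out
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
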