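#' Construct a single ontology concept
#'
#' A concept carries an HPO-style identifier, a preferred name, an ordered
#' vector of synonyms, and optional cross-references to foreign vocabularies
#' (e.g. SNOMED-CT). Synonyms are deduplicated case-sensitively on
#' construction and any synonym equal to the preferred name is dropped, so a
#' concept whose vocabulary entry lists the name among its synonyms (as
#' "Hearing impairment" does) keeps only the genuinely distinct surfaces.
#'
#' @param id Identifier string of the form `HP:` followed by seven digits.
#' @param name Preferred term; must be non-empty after trimming.
#' @param synonyms Character vector of synonym surfaces (may be empty).
#' @param xrefs Data frame with columns `source`, `foreign_id`, `term`
#'   (`term` may be `NA` when the cross-reference carries no surface string).
#' @return An object of class `hpo_concept`.
#' @export
#' @examples
#' concept("HP:0000365", "Hearing impairment",
#'         synonyms = c("Deafness", "Hearing loss"))
concept <- function(id, name, synonyms = character(), xrefs = empty_xrefs()) {
  if (!is_string(id) || !grepl(HP_ID_REGEX, id)) {
    stop("concept id must match 'HP:' + 7 digits, got: ", deparse(id))
  }
  if (!is_string(name) || !nzchar(trimws(name))) {
    stop("concept name must be a non-empty string (id ", id, ")")
  }
  name <- trimws(name)
  synonyms <- trimws(as.character(synonyms))
  synonyms <- synonyms[nzchar(synonyms)]
  synonyms <- unique(synonyms)
  synonyms <- synonyms[synonyms != name]
  stopifnot(is.data.frame(xrefs),
            all(c("source", "foreign_id", "term") %in% names(xrefs)))
  structure(
    list(id = id, name = name, synonyms = synonyms,
         xrefs = xrefs[, c("source", "foreign_id", "term"), drop = FALSE]),
    class = "hpo_concept"
  )
}

#' @rdname concept
#' @export
empty_xrefs <- function() {
  data.frame(source = character(), foreign_id = character(),
             term = character(), stringsAsFactors = FALSE)
}

#' Construct a vocabulary from a list of concepts
#'
#' @param concepts List of [concept()] objects; IDs must be unique.
#' @param source Provenance string (a file path or `"fixture:seed=N"`).
#' @return An object of class `hpo_vocabulary`. Iteration order is the order
#'   of `concepts` (document order for parsed files).
#' @export
vocabulary <- function(concepts, source = "in-memory") {
  stopifnot(is.list(concepts))
  ok <- vapply(concepts, inherits, logical(1), what = "hpo_concept")
  if (!all(ok)) stop("all elements of `concepts` must be hpo_concept objects")
  ids <- vapply(concepts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate concept IDs in vocabulary: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(concepts) <- ids
  structure(list(concepts = concepts, source = source),
            class = "hpo_vocabulary")
}

#' @export
length.hpo_vocabulary <- function(x) length(x$concepts)

#' @export
print.hpo_vocabulary <- function(x, ...) {
  n_syn <- sum(vapply(x$concepts, function(co) length(co$synonyms), integer(1)))
  n_xref <- sum(vapply(x$concepts, function(co) nrow(co$xrefs), integer(1)))
  cat(sprintf("<hpo_vocabulary> %d concepts, %d synonyms, %d xrefs (source: %s)\n",
              length(x), n_syn, n_xref, x$source))
  invisible(x)
}

#' @export
print.hpo_concept <- function(x, ...) {
  cat(sprintf("<hpo_concept> %s  %s  [%d synonyms, %d xrefs]\n",
              x$id, x$name, length(x$synonyms), nrow(x$xrefs)))
  invisible(x)
}

#' Vocabulary accessors
#'
#' `vocab_ids()` returns concept IDs in vocabulary order; `vocab_names()`
#' the preferred names.
#'
#' @param vocab An `hpo_vocabulary`.
#' @return A character vector, one element per concept.
#' @export
vocab_ids <- function(vocab) names(vocab$concepts)

#' @rdname vocab_ids
#' @export
vocab_names <- function(vocab) {
  unname(vapply(vocab$concepts, `[[`, character(1), "name"))
}

#' Flatten a vocabulary to a data frame
#'
#' @param x An `hpo_vocabulary`.
#' @param row.names,optional,... Ignored (base-R generic signature).
#' @return One row per concept: `id`, `name`, `synonyms` (pipe-joined),
#'   `xrefs` (pipe-joined `source:foreign_id:term`).
#' @export
as.data.frame.hpo_vocabulary <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    id = vocab_ids(x),
    name = vocab_names(x),
    synonyms = vapply(x$concepts, function(co) {
      paste(co$synonyms, collapse = "|")
    }, character(1)),
    xrefs = vapply(x$concepts, function(co) {
      if (nrow(co$xrefs) == 0L) return("")
      paste(sprintf("%s:%s:%s", co$xrefs$source, co$xrefs$foreign_id,
                    ifelse(is.na(co$xrefs$term), "", co$xrefs$term)),
            collapse = "|")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Parse an OBO-format vocabulary
#'
#' Reads OBO 1.2/1.4-style stanza text and returns one concept per
#' non-obsolete `[Term]` stanza with an `HP:`-prefixed identifier. Synonym
#' surfaces are the quoted portion of each `synonym:` line regardless of
#' scope tag (EXACT/BROAD/NARROW/RELATED). `xref:` lines are kept with their
#' source prefix, foreign ID and, when present, the trailing quoted surface
#' term. Obsolete terms, non-HP stanzas and malformed stanzas (missing id or
#' name) are skipped; skip counts are reported via [message()] and attached
#' as the `"skipped"` attribute.
#'
#' @param x Path to an OBO file, or a connection.
#' @return An `hpo_vocabulary` in document order.
#' @export
parse_obo <- function(x) {
  lines <- tryCatch(readLines(x, warn = FALSE),
                    error = function(e) stop("cannot read OBO input: ",
                                             conditionMessage(e)))
  src <- if (is_string(x)) x else "connection"

  # Stanza boundaries: any "[...]" header line.
  header_idx <- grep("^\\[[A-Za-z-]+\\]\\s*$", lines)
  skipped <- c(non_hp = 0L, obsolete = 0L, malformed = 0L)
  concepts <- list()
  k <- 0L
  for (i in seq_along(header_idx)) {
    start <- header_idx[i]
    end <- if (i < length(header_idx)) header_idx[i + 1L] - 1L else length(lines)
    if (trimws(lines[start]) != "[Term]") next
    body <- lines[(start + 1L):end]
    if (start + 1L > end) body <- character()

    grab1 <- function(pattern) {
      m <- regmatches(body, regexec(pattern, body))
      hits <- m[vapply(m, length, integer(1)) > 0L]
      if (length(hits) == 0L) NA_character_ else hits[[1L]][2L]
    }
    id <- grab1("^id:\\s*(\\S+)\\s*$")
    nm <- grab1("^name:\\s*(.+?)\\s*$")
    obsolete <- any(grepl("^is_obsolete:\\s*true", body))

    if (is.na(id) || is.na(nm) || !nzchar(trimws(nm))) {
      skipped["malformed"] <- skipped["malformed"] + 1L
      warning("skipping malformed [Term] stanza (missing id or name) near line ",
              start, call. = FALSE)
      next
    }
    if (!grepl(HP_ID_REGEX, id)) {
      skipped["non_hp"] <- skipped["non_hp"] + 1L
      next
    }
    if (obsolete) {
      skipped["obsolete"] <- skipped["obsolete"] + 1L
      next
    }

    syn_m <- regmatches(body, regexec("^synonym:\\s*\"([^\"]*)\"", body))
    syns <- vapply(syn_m[vapply(syn_m, length, integer(1)) > 0L],
                   `[[`, character(1), 2L)

    xr_m <- regmatches(
      body,
      regexec("^xref:\\s*([A-Za-z0-9_]+):(\\S+)(?:\\s+\"([^\"]*)\")?\\s*$", body)
    )
    xr_m <- xr_m[vapply(xr_m, length, integer(1)) > 0L]
    xr <- if (length(xr_m) == 0L) empty_xrefs() else data.frame(
      source = vapply(xr_m, `[[`, character(1), 2L),
      foreign_id = vapply(xr_m, `[[`, character(1), 3L),
      term = vapply(xr_m, function(m) {
        if (length(m) >= 4L && nzchar(m[4L])) m[4L] else NA_character_
      }, character(1)),
      stringsAsFactors = FALSE
    )

    k <- k + 1L
    concepts[[k]] <- concept(id, nm, synonyms = syns, xrefs = xr)
  }

  if (sum(skipped) > 0L) {
    message(sprintf(
      "parse_obo: skipped %d non-HP, %d obsolete, %d malformed stanza(s)",
      skipped["non_hp"], skipped["obsolete"], skipped["malformed"]))
  }
  out <- vocabulary(concepts, source = src)
  attr(out, "skipped") <- skipped
  out
}

#' Serialize a vocabulary to OBO text
#'
#' Writes one `[Term]` stanza per concept (id, name, `synonym: "..." EXACT []`
#' lines, `xref:` lines with the surface term quoted when present). Parsing
#' the output with [parse_obo()] recovers an equal vocabulary.
#'
#' @param vocab An `hpo_vocabulary`.
#' @param path Output file path, or `NULL` to return the lines invisibly only.
#' @return Invisibly, the character vector of OBO lines.
#' @export
write_obo <- function(vocab, path = NULL) {
  stopifnot(inherits(vocab, "hpo_vocabulary"))
  out <- c("format-version: 1.2", "")
  for (co in vocab$concepts) {
    stanza <- c("[Term]",
                paste0("id: ", co$id),
                paste0("name: ", co$name))
    if (length(co$synonyms)) {
      stanza <- c(stanza, sprintf("synonym: \"%s\" EXACT []", co$synonyms))
    }
    if (nrow(co$xrefs)) {
      stanza <- c(stanza, vapply(seq_len(nrow(co$xrefs)), function(i) {
        base <- sprintf("xref: %s:%s", co$xrefs$source[i], co$xrefs$foreign_id[i])
        if (!is.na(co$xrefs$term[i])) {
          base <- sprintf("%s \"%s\"", base, co$xrefs$term[i])
        }
        base
      }, character(1)))
    }
    out <- c(out, stanza, "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Write a vocabulary as TSV
#'
#' Columns: `id`, `name`, `synonyms` (pipe-joined), `xrefs` (pipe-joined).
#'
#' @param vocab An `hpo_vocabulary`.
#' @param path Output path.
#' @return Invisibly, the data frame written.
#' @export
write_vocab_tsv <- function(vocab, path) {
  df <- as.data.frame(vocab)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Extract cross-referenced surface terms as evaluation queries
#'
#' Returns one query per xref whose source prefix matches `prefix` and which
#' carries a surface term; the gold ID is the owning concept's ID and the
#' category is `XREF`. Cross-references without surface strings (OBO xref
#' lines often carry only foreign IDs) are skipped.
#'
#' @param vocab An `hpo_vocabulary`.
#' @param prefix Source prefix to match, e.g. `"SNOMEDCT_US"`.
#' @return A data frame of query items: `term`, `gold_id`, `category`,
#'   `source_term` (always `NA` here).
#' @export
extract_xref_terms <- function(vocab, prefix = "SNOMEDCT_US") {
  stopifnot(inherits(vocab, "hpo_vocabulary"), is_string(prefix), nzchar(prefix))
  rows <- lapply(vocab$concepts, function(co) {
    xr <- co$xrefs
    xr <- xr[xr$source == prefix & !is.na(xr$term), , drop = FALSE]
    if (nrow(xr) == 0L) return(NULL)
    data.frame(term = xr$term, gold_id = co$id, category = "XREF",
               source_term = NA_character_, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term = character(), gold_id = character(),
                      category = character(), source_term = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Word pool for synthetic pseudo-phenotype phrases. Mixing anatomy,
# descriptors and findings gives multi-word names whose token overlap makes
# token-based retrieval nontrivial.
fixture_word_pool <- function() {
  c(
    "kidney", "renal", "cardiac", "hepatic", "ocular", "retinal", "cranial",
    "facial", "digital", "femoral", "spinal", "neural", "dermal", "nasal",
    "aortic", "atrial", "cortical", "hippocampal", "auditory", "vascular",
    "skeletal", "muscular", "pulmonary", "gastric", "pancreatic", "thyroid",
    "adrenal", "ureteral", "vertebral", "humeral", "mandibular", "palatal",
    "abnormal", "absent", "hypoplastic", "aplastic", "dysplastic", "atrophic",
    "enlarged", "reduced", "elongated", "shortened", "broad", "narrow",
    "thickened", "fused", "cleft", "ectopic", "cystic", "calcified",
    "dilated", "stenotic", "tortuous", "fragile", "sparse", "coarse",
    "delayed", "recurrent", "progressive", "congenital", "bilateral",
    "unilateral", "proximal", "distal", "generalized", "focal", "severe",
    "mild", "intermittent",
    "impairment", "degeneration", "malformation", "dysfunction", "weakness",
    "stiffness", "laxity", "swelling", "lesion", "nodule", "opacity",
    "pigmentation", "inflammation", "hemorrhage", "seizure", "tremor",
    "ataxia", "spasticity", "deafness", "blindness", "anomaly", "agenesis",
    "hypertrophy", "atrophy", "dysplasia", "stenosis", "dilatation",
    "fragility"
  )
}

#' Generate a synthetic test vocabulary
#'
#' Builds a deterministic pseudo-HPO vocabulary for testing without any
#' download. IDs are `HP:` + zero-padded sequential 7-digit numbers. Names
#' and synonyms are 2–5-token pseudo-phenotype phrases drawn from a built-in
#' word list; within a phrase tokens are distinct, and across the whole
#' vocabulary every name and synonym has a globally unique token set, so
#' exact-name retrieval has a single best answer. A fraction `xref_rate` of
#' concepts carries one synthetic SNOMED-style cross-reference whose surface
#' term is hyphenated (`"Kidney - Abnormal"` style), exercising hyphen
#' normalization.
#'
#' @param n_concepts Number of concepts (>= 1).
#' @param synonyms_per_concept Integer range `c(lo, hi)` with
#'   `0 <= lo <= hi <= 8`; each concept's synonym count is drawn uniformly
#'   from the range.
#' @param xref_rate Probability in \[0, 1\] that a concept carries an xref.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return An `hpo_vocabulary` with `source = "fixture:seed=<seed>"`.
#' @export
#' @examples
#' v <- generate_fixture(20, c(2, 4), xref_rate = 0.5, seed = 7)
#' v
generate_fixture <- function(n_concepts, synonyms_per_concept = c(2, 4),
                             xref_rate = 0, seed = 1) {
  if (!is.numeric(n_concepts) || length(n_concepts) != 1L || n_concepts < 1) {
    stop("n_concepts must be a positive integer")
  }
  if (length(synonyms_per_concept) != 2L ||
      !is.numeric(synonyms_per_concept) ||
      synonyms_per_concept[1] < 0 ||
      synonyms_per_concept[1] > synonyms_per_concept[2] ||
      synonyms_per_concept[2] > 8) {
    stop("synonyms_per_concept must be c(lo, hi) with 0 <= lo <= hi <= 8")
  }
  if (!is.numeric(xref_rate) || xref_rate < 0 || xref_rate > 1) {
    stop("xref_rate must be a probability in [0, 1]")
  }
  n_concepts <- as.integer(n_concepts)
  lo <- as.integer(synonyms_per_concept[1])
  hi <- as.integer(synonyms_per_concept[2])
  pool <- fixture_word_pool()

  with_seed(seed, {
    used_keys <- new.env(parent = emptyenv())
    draw_phrase <- function() {
      for (attempt in 1:1000) {
        len <- sample.int(4L, 1L) + 1L  # 2..5 tokens
        words <- sample_values(pool, len)
        key <- paste(sort(words), collapse = " ")
        if (!exists(key, envir = used_keys, inherits = FALSE)) {
          assign(key, TRUE, envir = used_keys)
          return(capitalize(paste(words, collapse = " ")))
        }
      }
      stop("could not draw a unique phrase; word pool exhausted")
    }
    concepts <- vector("list", n_concepts)
    for (i in seq_len(n_concepts)) {
      nm <- draw_phrase()
      n_syn <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
      syns <- if (n_syn > 0L) {
        vapply(seq_len(n_syn), function(j) draw_phrase(), character(1))
      } else character()
      xr <- if (stats::runif(1) < xref_rate) {
        parts <- capitalize(sample_values(pool, 2L))
        data.frame(source = "SNOMEDCT_US",
                   foreign_id = sprintf("%06d", sample.int(999999L, 1L)),
                   term = paste(parts, collapse = " - "),
                   stringsAsFactors = FALSE)
      } else {
        empty_xrefs()
      }
      concepts[[i]] <- concept(sprintf("HP:%07d", i), nm,
                               synonyms = syns, xrefs = xr)
    }
    vocabulary(concepts, source = sprintf("fixture:seed=%d", as.integer(seed)))
  })
}
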