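make_eval_fixture <- function(n = 20, syn = c(3, 3), seed = 60) {
  v <- generate_fixture(n, syn, xref_rate = 0.5, seed = seed)
  corpus <- build_name_syn_corpus(v, seed = seed + 1)
  queries <- build_query_sets(v, held_out = corpus$held_out,
                              xrefs = extract_xref_terms(v),
                              seed = seed + 2)
  list(vocab = v, corpus = corpus, queries = queries)
}

test_that("query sets carry the expected categories and counts", {
  fx <- make_eval_fixture(20, c(3, 3))
  tab <- table(fx$queries$category)
  expect_equal(unname(tab[["TRAIN_NAME"]]), 20L)
  expect_equal(unname(tab[["SIMPLE_TYPO"]]), 20L)
  expect_equal(unname(tab[["COMPLEX_TYPO"]]), 20L)
  # 3 synonyms -> ceiling(3/2) = 2 held out per concept
  expect_equal(unname(tab[["HELD_OUT_SYNONYM"]]), 40L)
  expect_false("LAYMEN" %in% names(tab))  # no laymen file given
  # every typo query is a true perturbation of a known name
  typo <- fx$queries[fx$queries$category == "SIMPLE_TYPO", ]
  for (i in seq_len(nrow(typo))) {
    expect_equal(hamming(typo$source_term[i], typo$term[i]), 1L)
    expect_true(typo$source_term[i] %in% vocab_names(fx$vocab))
    expect_false(typo$term[i] == typo$source_term[i])
  }
  # gold IDs all exist in the vocabulary
  expect_true(all(fx$queries$gold_id %in% vocab_ids(fx$vocab)))
})

test_that("query building is deterministic per seed", {
  fx1 <- make_eval_fixture(10, c(2, 2), seed = 70)
  fx2 <- make_eval_fixture(10, c(2, 2), seed = 70)
  expect_identical(fx1$queries, fx2$queries)
})

test_that("laymen terms load from TSV and unknown gold IDs are dropped with a warning", {
  v <- generate_fixture(5, c(0, 0), seed = 80)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(term = c("trouble hearing", "made up"),
                         gold_id = c("HP:0000001", "HP:9999999")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(
    q <- build_query_sets(v, laymen = path, seed = 1),
    "1 laymen row"
  )
  lay <- q[q$category == "LAYMEN", ]
  expect_equal(nrow(lay), 1L)
  expect_equal(lay$term, "trouble hearing")
})

test_that("accuracy is bounded by the oracle sandwich and counts conserve", {
  fx <- make_eval_fixture()
  gold <- stats::setNames(fx$queries$gold_id, fx$queries$term)
  oracle <- function(term) unname(gold[term])
  nothing <- function(term) NA_character_
  idx <- build_index(fx$vocab)

  r_top <- evaluate_normalizer(oracle, fx$queries, id = "oracle")
  r_bot <- evaluate_normalizer(nothing, fx$queries, id = "none")
  r_mid <- evaluate_normalizer(bm25_normalizer(idx, "OR"), fx$queries, "bm25")

  expect_true(all(r_top$rows$accuracy == 1))
  expect_true(all(r_bot$rows$accuracy == 0))
  expect_equal(r_bot$rows$n_no_prediction, r_bot$rows$n_total)
  expect_true(all(r_mid$rows$accuracy >= 0 & r_mid$rows$accuracy <= 1))
  for (r in list(r_top, r_bot, r_mid)) {
    expect_true(all(r$rows$n_correct + r$rows$n_no_prediction <= r$rows$n_total))
    expect_equal(nrow(r$outcomes), nrow(fx$queries))
  }
})

test_that("normalizer exceptions are recorded as no-prediction and the run continues", {
  fx <- make_eval_fixture(5, c(0, 0))
  flaky <- local({
    i <- 0
    function(term) {
      i <<- i + 1
      if (i %% 2 == 0) stop("boom")
      fx$queries$gold_id[match(term, fx$queries$term)]
    }
  })
  r <- evaluate_normalizer(flaky, fx$queries)
  expect_gt(sum(r$rows$n_no_prediction), 0)
  expect_equal(sum(r$rows$n_total), nrow(fx$queries))
})

test_that("near-miss digit suffix mismatches are diagnostic only", {
  q <- data.frame(term = c("a", "b", "c"),
                  gold_id = c("HP:0000365", "HP:0000365", "HP:0000365"),
                  category = "TRAIN_NAME", source_term = NA,
                  stringsAsFactors = FALSE)
  answers <- c(a = "HP:0000365", b = "HP:0000367", c = "HP:0100365")
  r <- evaluate_normalizer(function(t) answers[[t]], q)
  expect_equal(r$outcomes$digit_suffix_mismatch, c(NA, 1L, 6L))
  expect_equal(r$rows$accuracy, 1 / 3)  # no partial credit
})

test_that("held-out synonyms never appear among NAME+SYN training terms", {
  fx <- make_eval_fixture(30, c(1, 5), seed = 90)
  train_terms <- fx$corpus$sentences$term
  held <- fx$queries$term[fx$queries$category == "HELD_OUT_SYNONYM"]
  expect_length(intersect(held, train_terms), 0L)
})

test_that("reports render as Table-1-style percentages and TSV round-trips", {
  fx <- make_eval_fixture(10, c(2, 2))
  idx <- build_index(fx$vocab)
  r <- evaluate_normalizer(bm25_normalizer(idx, "AND"), fx$queries, "bm25-and")
  txt <- write_report(r, format = "text")
  expect_match(txt[1], "accuracy")
  expect_match(paste(txt, collapse = "\n"), "\\d+\\.\\d%")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(r, path, format = "tsv")
  back <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(accuracy_pct = "character"))
  expect_equal(nrow(back), nrow(r$rows))
  expect_identical(back$accuracy_pct, sprintf("%.1f", 100 * r$rows$accuracy))
  expect_equal(back$n_correct, r$rows$n_correct)
})

test_that("prompt robustness: memorizing stub is perfect on its template, brittle on rewording", {
  v <- generate_fixture(10, c(0, 0), seed = 95)
  recs <- make_records(build_name_corpus(v))
  stub <- lookup_model(recs)
  queries <- build_query_sets(v, seed = 1)
  queries <- queries[queries$category == "TRAIN_NAME", ]
  rep <- prompt_robustness(stub, queries)
  rows <- rep$rows
  expect_equal(nrow(rows), 2L)
  expect_equal(rows$accuracy[rows$template == hpo_prompt_template()], 1)
  expect_equal(rows$accuracy[rows$template == alt_prompt_template()], 0)
  expect_identical(rep$metadata$templates,
                   c(hpo_prompt_template(), alt_prompt_template()))
})
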