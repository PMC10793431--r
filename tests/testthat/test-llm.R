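test_that("records split after 'HPO ID ' and reconstruct sentences losslessly", {
  v <- generate_fixture(15, c(0, 4), seed = 5)
  for (corpus in list(build_name_corpus(v),
                      build_name_syn_corpus(v, seed = 2),
                      build_typo_corpus(build_name_corpus(v), seed = 3))) {
    recs <- make_records(corpus)
    expect_equal(nrow(recs), nrow(corpus$sentences))
    expect_identical(paste0(recs$prompt, recs$completion),
                     corpus$sentences$text)
    expect_true(all(endsWith(recs$prompt, "HPO ID ")))
    expect_true(all(grepl("^HP:[0-9]{7}$", recs$completion)))
  }
  s <- render_sentence("Hearing impairment", "HP:0000365")
  r <- make_records(structure(list(sentences = s, variant = "NAME",
                                   held_out = data.frame(term = character(),
                                                         concept_id = character()),
                                   seed = NA), class = "hpo_corpus"))
  expect_identical(r$completion, "HP:0000365")
  expect_true(endsWith(r$prompt, "identified by the HPO ID "))
})

test_that("non-template sentences are rejected with the offending line", {
  bad <- structure(list(
    sentences = data.frame(text = "No identifier marker here",
                           term = "x", concept_id = "HP:0000001",
                           origin = "NAME", stringsAsFactors = FALSE),
    variant = "NAME",
    held_out = data.frame(term = character(), concept_id = character()),
    seed = NA), class = "hpo_corpus")
  expect_error(make_records(bad), "No identifier marker here")
})

test_that("empty corpus gives an empty record list", {
  empty <- structure(list(
    sentences = data.frame(text = character(), term = character(),
                           concept_id = character(), origin = character()),
    variant = "NAME",
    held_out = data.frame(term = character(), concept_id = character()),
    seed = NA), class = "hpo_corpus")
  expect_equal(nrow(make_records(empty)), 0L)
})

test_that("HPO IDs are extracted from arbitrary generated text", {
  expect_equal(extract_hpo_id("HP:0000365."), "HP:0000365")
  expect_equal(extract_hpo_id("the ID is HP:0012824 which corresponds to Severity"),
               "HP:0012824")
  expect_equal(extract_hpo_id("hp:0000001 lowercased"), "HP:0000001")
  expect_true(is.na(extract_hpo_id("an arbitrary string of numbers 4711")))
  expect_true(is.na(extract_hpo_id("HP:123 too short")))
  # first match wins; idempotent on its own output
  two <- extract_hpo_id("HP:0000001 then HP:0000002")
  expect_equal(two, "HP:0000001")
  expect_equal(extract_hpo_id(two), two)
  # vectorized
  expect_equal(extract_hpo_id(c("x HP:0000005", "none")),
               c("HP:0000005", NA))
})

test_that("a memorizing stub is perfect on training prompts, a constant stub scores zero", {
  v <- generate_fixture(12, c(0, 0), seed = 30)
  recs <- make_records(build_name_corpus(v))
  stub <- lookup_model(recs)
  norm <- completion_normalizer(stub)
  nms <- vocab_names(v)
  preds <- vapply(nms, norm, character(1))
  expect_identical(unname(preds), vocab_ids(v))

  none <- completion_normalizer(constant_model("hello"))
  expect_true(all(is.na(vapply(nms, none, character(1)))))
})

test_that("alternate prompt templates render correctly", {
  stub <- constant_model("HP:0000001")
  norm <- completion_normalizer(stub, "HPO ID of {term} is ")
  expect_equal(norm("anything"), "HP:0000001")
  expect_error(completion_normalizer(stub, "no placeholder"), "placeholder")
})

test_that("fine-tuning a non-trainable model is a capability error", {
  recs <- data.frame(prompt = "p HPO ID ", completion = "HP:0000001",
                     text = "p HPO ID HP:0000001")
  expect_error(finetune(constant_model(), recs), "does not support")
})

test_that("zero-epoch fine-tuning returns the model unchanged with an empty trace", {
  m <- char_lm(context_len = 8, hidden_dim = 16, seed = 1)
  recs <- data.frame(text = "ab", prompt = "a", completion = "b")
  out <- finetune(m, recs, finetune_config(epochs = 0))
  expect_identical(out$model$params, m$params)
  expect_length(out$loss, 0L)
})

test_that("the char-level model trains reproducibly and reduces loss", {
  v <- generate_fixture(5, c(0, 0), seed = 41)
  recs <- make_records(build_name_corpus(v))
  m <- char_lm(context_len = 48, embed_dim = 8, hidden_dim = 64, seed = 7)
  expect_lt(m$n_params, 1e6)
  cfg <- finetune_config(epochs = 15, batch_size = 64, seed = 9)
  a <- finetune(m, recs, cfg)
  b <- finetune(m, recs, cfg)
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$loss, b$loss)
  expect_length(a$loss, 15L)
  expect_lt(a$loss[15], a$loss[1])
})

test_that("training records round-trip through JSONL", {
  v <- generate_fixture(6, c(0, 1), seed = 50)
  recs <- make_records(build_name_syn_corpus(v, seed = 1))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_records_jsonl(recs, path)
  back <- read_records_jsonl(path)
  expect_identical(back, recs[, c("text", "prompt", "completion")])
})
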