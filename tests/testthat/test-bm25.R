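test_that("tokenization lowercases, splits on non-alphanumerics and drops empties", {
  expect_equal(tokenize_term("Kidney - Abnormal"), c("kidney", "abnormal"))
  expect_equal(tokenize_term("Low-set, posteriorly rotated ears"),
               c("low", "set", "posteriorly", "rotated", "ears"))
  expect_equal(tokenize_term(""), character())
  expect_equal(tokenize_term("  --  "), character())
  # hyphen stripping commutes with tokenization
  v <- generate_fixture(20, c(1, 3), xref_rate = 1, seed = 2)
  terms <- c(vocab_entries(v)$terms, extract_xref_terms(v)$term)
  for (t in terms) {
    expect_identical(tokenize_term(strip_hyphens(t)), tokenize_term(t))
  }
})

test_that("the index holds one entry per (name or synonym, concept) pair", {
  v <- generate_fixture(50, c(3, 3), seed = 7)
  idx <- build_index(v)
  expect_equal(idx$N, 200L)
  expect_equal(nrow(idx$entries), 200L)
  # document frequencies agree with a brute-force scan
  toks <- lapply(idx$entries$term, tokenize_term)
  for (t in sample(names(idx$df), 25)) {
    expect_equal(unname(idx$df[t]),
                 sum(vapply(toks, function(x) t %in% x, logical(1))))
  }
  expect_error(build_index(vocabulary(list())), "empty")
})

test_that("a single-entry index scores its own tokens by the closed form", {
  v <- vocabulary(list(concept("HP:0000001", "renal cystic dysplasia")))
  idx <- build_index(v)
  q <- c("renal", "cystic", "dysplasia")
  # N = 1, df = 1, len = avglen = 3, tf = 1 per token:
  idf <- log(1 + (1 - 1 + 0.5) / (1 + 0.5))
  per_token <- idf * 1 * (1.2 + 1) / (1 + 1.2 * (1 - 0.75 + 0.75 * 3 / 3))
  expect_equal(bm25_score(idx, q, 1), 3 * per_token, tolerance = 1e-12)
  # disjoint query scores zero
  expect_equal(bm25_score(idx, c("cardiac"), 1), 0)
  # identity retrieval under both modes
  expect_equal(normalize_term(idx, "renal cystic dysplasia", "AND"), "HP:0000001")
  expect_equal(normalize_term(idx, "renal cystic dysplasia", "OR"), "HP:0000001")
})

test_that("term-frequency saturation is monotone but sublinear", {
  v <- vocabulary(list(
    concept("HP:0000001", "renal", synonyms = c("renal renal", "renal renal renal")),
    concept("HP:0000002", "cardiac atrophy")
  ))
  idx <- build_index(v)
  # entries 1..3 have tf(renal) = 1, 2, 3 and increasing length
  s <- vapply(1:3, function(e) bm25_score(idx, "renal", e), numeric(1))
  gain1 <- s[2] - s[1]
  gain2 <- s[3] - s[2]
  expect_lt(gain2, gain1)
})

test_that("normalize_term agrees with the brute-force oracle on random fixtures", {
  set.seed(71)
  for (rep in 1:20) {
    v <- generate_fixture(sample(3:10, 1), c(0, 2), seed = 1000 + rep)
    ent <- vocab_entries(v)
    idx <- build_index(v)
    queries <- c(
      sample(ent$terms, min(4, length(ent$terms))),
      vapply(sample(ent$terms, 3), function(t) simple_typo(t), character(1)),
      "renal cardiac", "nonexistent tokens only", ""
    )
    for (q in queries) {
      for (mode in c("AND", "OR")) {
        expect_identical(normalize_term(idx, q, mode),
                         oracle_normalize(ent$terms, ent$ids, q, mode),
                         label = sprintf("query '%s' mode %s rep %d", q, mode, rep))
      }
    }
  }
})

test_that("AND candidates are a subset of OR candidates", {
  v <- generate_fixture(40, c(0, 3), seed = 15)
  idx <- build_index(v)
  ent <- vocab_entries(v)
  set.seed(5)
  pool <- unique(unlist(lapply(ent$terms, tokenize_term)))
  for (i in 1:200) {
    q <- paste(sample(pool, sample(1:4, 1)), collapse = " ")
    and_id <- normalize_term(idx, q, "AND")
    or_id <- normalize_term(idx, q, "OR")
    if (!is.na(and_id)) expect_false(is.na(or_id))
  }
})

test_that("a mistyped token defeats AND but OR can recover via intact tokens", {
  v <- generate_fixture(100, c(0, 0), seed = 21)
  idx <- build_index(v)
  nms <- vocab_names(v)
  multi <- nms[lengths(lapply(nms, tokenize_term)) >= 2]
  set.seed(31)
  typos <- vapply(multi, function(t) simple_typo(t), character(1))
  and_acc <- mean(vapply(seq_along(multi), function(i) {
    identical(normalize_term(idx, typos[i], "AND"), vocab_ids(v)[match(multi[i], nms)])
  }, logical(1)))
  or_acc <- mean(vapply(seq_along(multi), function(i) {
    identical(normalize_term(idx, typos[i], "OR"), vocab_ids(v)[match(multi[i], nms)])
  }, logical(1)))
  expect_gt(or_acc, and_acc)
})

test_that("retrieval is deterministic including tie-breaks", {
  # two concepts share an identical token set surface -> tie broken by
  # lexicographically smallest concept ID
  v <- vocabulary(list(
    concept("HP:0000002", "cystic renal"),
    concept("HP:0000001", "renal cystic")
  ))
  idx <- build_index(v)
  expect_equal(normalize_term(idx, "renal cystic", "AND"), "HP:0000001")
  expect_equal(normalize_term(idx, "cystic renal", "OR"), "HP:0000001")
  # empty query -> no prediction
  expect_identical(normalize_term(idx, "...", "OR"), NA_character_)
})

test_that("the index persists to JSON and reloads equivalently", {
  v <- generate_fixture(20, c(1, 3), seed = 17)
  idx <- build_index(v)
  path <- withr::local_tempfile(fileext = ".json")
  save_index(idx, path)
  idx2 <- load_index(path)
  expect_identical(idx$entries, idx2$entries)
  expect_equal(idx$df, idx2$df)
  nms <- vocab_names(v)
  for (t in nms[1:5]) {
    expect_identical(normalize_term(idx, t, "OR"), normalize_term(idx2, t, "OR"))
  }
  expect_error(load_index(withr::local_tempfile(lines = "{\"format\":\"x\"}",
                                                fileext = ".json")),
               "not a phenonorm")
})
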