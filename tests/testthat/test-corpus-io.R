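post_line <- function(id, text = "I take gabapentin for pain.",
                      drug = "gabapentin", source = "medhelp") {
  jsonlite::toJSON(list(post_id = id, source = source, drug_keyword = drug,
                        text = text), auto_unbox = TRUE)
}

test_that("read_posts returns posts in file order and validates records", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), f)
  expect_equal(nrow(read_posts(f)), 0L)

  writeLines(c(post_line("a"), post_line("b"), post_line("c")), f)
  posts <- read_posts(f)
  expect_equal(posts$post_id, c("a", "b", "c"))
  expect_equal(nrow(posts), 3L)

  bad <- jsonlite::toJSON(list(post_id = "x", source = "webmd",
                               drug_keyword = "gabapentin"), auto_unbox = TRUE)
  writeLines(c(post_line("a"), bad), f)
  expect_error(read_posts(f), "line 2.*text")

  writeLines(c(post_line("a"), post_line("a")), f)
  expect_error(read_posts(f), "duplicate post_id")
})

test_that("record writing round-trips losslessly in both formats", {
  recs <- data.frame(
    post_id = paste0("p", 1:5), drug = "lorazepam",
    indication = c("sleep_disorder_insomnia", "pain", "anxiety",
                   "panic_attacks", "a, quoted, indication"),
    off_label = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    confidence = c("high", "medium", "low", "high", "high"),
    jump_distance = c(2L, 7L, 3L, 4L, 1L),
    same_sentence = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    substitution_used = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    negated = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  for (fmt in c("csv", "jsonl")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_records(recs, f, fmt)
    back <- read_records(f, fmt)
    expect_equal(back, recs, ignore_attr = TRUE)
  }
  # commas inside fields survive CSV quoting
  f <- withr::local_tempfile(fileext = ".csv")
  write_records(recs, f, "csv")
  expect_equal(read_records(f, "csv")$indication[5], "a, quoted, indication")
  # empty record list -> header-only CSV
  write_records(recs[0, ], f, "csv")
  expect_equal(length(readLines(f)), 1L)
  expect_equal(nrow(read_records(f, "csv")), 0L)
})

test_that("ground truth sidecar round-trips including planted pairs", {
  corp <- separable_corpus(30L, seed = 5L)$corpus
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_ground_truth(corp$truth, f)
  back <- read_ground_truth(f)
  expect_equal(back$post_id, corp$truth$post_id)
  expect_equal(back$relevant, corp$truth$relevant)
  expect_equal(back$off_label_truth, corp$truth$off_label_truth)
  i <- which(back$relevant)[1]
  expect_equal(back$planted_pairs[[i]]$indication,
               corp$truth$planted_pairs[[i]]$indication)
})

test_that("generator honours size, determinism and the relevance fraction", {
  lex <- fixture_lexicon(); lm <- fixture_label_map()
  empty <- generate_synthetic_corpus(generator_config(0), lex, lm)
  expect_equal(nrow(empty$posts), 0L)
  expect_equal(nrow(empty$truth), 0L)

  a <- generate_synthetic_corpus(generator_config(50, seed = 1), lex, lm)
  b <- generate_synthetic_corpus(generator_config(50, seed = 1), lex, lm)
  expect_identical(a, b)

  big <- generate_synthetic_corpus(generator_config(1000, seed = 7), lex, lm)
  # binomial bound: within 3 sd of 700 (sd = sqrt(1000 * 0.7 * 0.3) ~ 14.5)
  expect_lt(abs(sum(big$truth$relevant) - 700), 3 * sqrt(1000 * 0.7 * 0.3))
})

test_that("planted truth is consistent with the label map", {
  lex <- fixture_lexicon(); lm <- fixture_label_map()
  corp <- generate_synthetic_corpus(generator_config(400, seed = 3), lex, lm)
  for (i in seq_len(nrow(corp$truth))) {
    pair <- corp$truth$planted_pairs[[i]]
    if (is.null(pair)) next
    expect_equal(pair$drug, corp$posts$drug_keyword[i])
    if (corp$truth$off_label_truth[i]) {
      expect_false(pair$indication %in% lm$approved[[pair$drug]])
      expect_false(pair$negated)
    }
  }
  # off-label truth implies relevance
  expect_true(all(corp$truth$relevant[corp$truth$off_label_truth]))
})

test_that("injected misspellings stay recoverable within two edits", {
  lex <- fixture_lexicon(); lm <- fixture_label_map()
  corp <- generate_synthetic_corpus(
    generator_config(80, seed = 13, misspell_rate = 1), lex, lm)
  vocab <- unique(c(offlabelr:::lexicon_token_vocabulary(lex)))
  for (text in corp$posts$text) {
    toks <- tokenize(text)
    oov <- setdiff(toks[nchar(toks) >= 4], vocab)
    for (tok in oov) {
      expect_lte(min(utils::adist(tok, vocab)), 2)
    }
  }
})
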