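test_that("count vectorization counts terms and respects feature caps", {
  r <- vectorize(c("a b", "a"), vectorizer_spec("count", max_features = 10))
  expect_equal(unname(r$matrix[, "a"]), c(1, 1))
  expect_equal(unname(r$matrix[, "b"]), c(1, 0))

  texts <- separable_corpus(80, seed = 2)$texts
  r <- vectorize(texts, vectorizer_spec("count_plus_tfidf", max_features = 900))
  expect_lte(ncol(r$matrix), 900)
  expect_lte(sum(grepl("^count_", colnames(r$matrix))), 450)
  expect_lte(sum(grepl("^tfidf_", colnames(r$matrix))), 450)
  expect_lte(length(r$vectorizer$vocabulary), 450)

  # refit on the same corpus is identical
  r2 <- vectorize(texts, vectorizer_spec("count_plus_tfidf", max_features = 900))
  expect_identical(r$matrix, r2$matrix)
  expect_error(vectorize(character(), vectorizer_spec("count")), "empty corpus")
})

test_that("a ubiquitous term never outweighs an equally frequent rarer term", {
  # three-document fixture, idf computable by hand:
  # "common" in all 3 docs, "rare" in 1; both once per containing doc
  texts <- c("common rare", "common filler", "common filler")
  r <- vectorize(texts, vectorizer_spec("tfidf", max_features = 10))
  idf_common <- log((1 + 3) / (1 + 3)) + 1   # = 1
  idf_rare <- log((1 + 3) / (1 + 1)) + 1     # = 1 + log 2
  expect_equal(unname(r$matrix[1, "common"]), idf_common)
  expect_equal(unname(r$matrix[1, "rare"]), idf_rare)
  expect_lte(r$matrix[1, "common"], r$matrix[1, "rare"])
})

test_that("document-embedding scheme yields capped dense vectors", {
  texts <- separable_corpus(60, seed = 8)$texts
  r <- vectorize(texts, vectorizer_spec("doc_embedding", max_features = 32))
  expect_lte(ncol(r$matrix), 32)
  expect_equal(nrow(r$matrix), length(texts))
  m2 <- vectorize_transform(r$vectorizer, texts[1:5])
  expect_equal(m2, r$matrix[1:5, , drop = FALSE], ignore_attr = TRUE)
})

test_that("training rejects degenerate inputs", {
  texts <- c("a b", "a c", "b c", "a")
  expect_error(train_relevance_classifier(texts, rep(TRUE, 4)),
               "single class")
  expect_error(train_relevance_classifier(character(), logical()), "empty")
  expect_error(train_relevance_classifier(texts, c(TRUE, FALSE)), "length")
})

test_that("the classifier recovers planted relevance signal deterministically", {
  sc <- separable_corpus(200, seed = 11)
  cfg <- train_config(seed = 42)
  m1 <- train_relevance_classifier(sc$texts, sc$labels, cfg = cfg)
  expect_s3_class(m1, "relevance_model")
  expect_gt(m1$metrics$accuracy, 0.9)
  # determinism: identical metrics on a re-run with the same seed
  m2 <- train_relevance_classifier(sc$texts, sc$labels, cfg = cfg)
  expect_equal(m1$metrics, m2$metrics)
  # a post matching a relevant template classifies as relevant
  expect_true(classify_relevance(m1, "I take gabapentin for my pain."))
  # purity and empty input
  texts <- sc$texts[1:10]
  expect_identical(classify_relevance(m1, texts),
                   classify_relevance(m1, texts))
  expect_equal(classify_relevance(m1, character()), logical())
  expect_error(classify_relevance(list(), "x"), "not a fitted")
})

test_that("alternative classifier backends train and predict", {
  sc <- separable_corpus(120, seed = 19)
  for (clf in c("svm", "naive_bayes", "sgd_linear", "random_forest")) {
    m <- train_relevance_classifier(
      sc$texts, sc$labels,
      spec = vectorizer_spec("count", max_features = 200),
      cfg = train_config(classifier = clf, seed = 3))
    expect_gt(m$metrics$accuracy, 0.7)
  }
})

test_that("model persistence round-trips through a single file", {
  sc <- separable_corpus(100, seed = 29)
  m <- train_relevance_classifier(sc$texts, sc$labels,
                                  cfg = train_config(seed = 1))
  f <- withr::local_tempfile(fileext = ".rds")
  save_relevance_model(m, f)
  m2 <- load_relevance_model(f)
  expect_identical(classify_relevance(m2, sc$texts[1:20]),
                   classify_relevance(m, sc$texts[1:20]))
})

test_that("cross-validation folds partition the data", {
  sc <- separable_corpus(100, seed = 11)
  cv <- kfold_cv(sc$texts, sc$labels,
                 spec = vectorizer_spec("count", max_features = 300),
                 cfg = train_config(k_folds = 10, seed = 7))
  expect_equal(length(cv$folds), 10L)
  expect_equal(as.integer(table(cv$assignments)), rep(10L, 10))
  expect_equal(sort(unique(cv$assignments)), 1:10)
  expect_error(kfold_cv("one", TRUE, cfg = train_config(k_folds = 2)),
               "exceeds")
})

test_that("the selected model clears a majority-class baseline by 20 points", {
  sc <- separable_corpus(200, seed = 11)
  m <- train_relevance_classifier(sc$texts, sc$labels,
                                  cfg = train_config(seed = 5))
  baseline <- max(mean(sc$labels), 1 - mean(sc$labels))
  expect_gte(m$metrics$accuracy - baseline, 0.2)
})
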