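test_that("sentence splitting is deterministic and terminator-aware", {
  expect_equal(split_sentences(""), character())
  expect_equal(split_sentences("One sentence only"), "One sentence only")
  expect_equal(
    split_sentences("My doctor prescribed quetiapine. It works for my insomnia."),
    c("My doctor prescribed quetiapine.", "It works for my insomnia."))
  # no split without a following capitalized sentence start
  expect_equal(length(split_sentences("posted on drugs.com yesterday")), 1L)
})

test_that("recognizer applies greedy longest match with non-overlapping spans", {
  lex <- fixture_lexicon()
  expect_equal(nrow(recognize_entities("", lex)), 0L)

  m <- recognize_entities("I take gabapentin for nerve pain", lex, "p1")
  expect_equal(nrow(m), 2L)
  expect_equal(m$surface, c("gabapentin", "nerve pain"))
  expect_equal(m$category, c("drug", "indication"))
  expect_equal(m$concept_id[2], "neuropathic_pain")  # not bare "pain"

  m <- recognize_entities("pain pain", lex)
  expect_equal(nrow(m), 2L)
  expect_true(m$end[1] <= m$start[2])  # disjoint spans

  # spans never overlap on a busier sentence
  m <- recognize_entities(
    "I take pregabalin for diabetic peripheral neuropathy and nerve pain", lex)
  ord <- order(m$start)
  expect_true(all(m$end[ord][-nrow(m)] <= m$start[ord][-1]))
})

test_that("recognizer recall on planted mentions is complete", {
  lex <- fixture_lexicon(); lm <- fixture_label_map()
  # exact-coverage condition: no injected misspellings
  corp <- generate_synthetic_corpus(
    generator_config(150, seed = 17, misspell_rate = 0), lex, lm)
  surfaces <- offlabelr:::concept_surfaces(lex)
  for (i in seq_len(nrow(corp$truth))) {
    pair <- corp$truth$planted_pairs[[i]]
    if (is.null(pair)) next
    m <- recognize_entities(corp$posts$text[i], lex)
    expect_true(pair$drug %in% m$concept_id[m$category == "drug"])
    expect_true(pair$indication %in% m$concept_id[m$category == "indication"])
  }
})

test_that("embedding training is deterministic and shape-correct", {
  corpus <- rep(list(c("druga", "conda", "filler"),
                     c("noisez", "other", "filler")), 20)
  a <- train_embeddings(corpus, d = 8, seed = 4)
  b <- train_embeddings(corpus, d = 8, seed = 4)
  expect_identical(a, b)
  expect_true(all(vapply(seq_len(nrow(a$vectors)),
                         function(i) length(a$vectors[i, ]), integer(1)) == 8L))
  expect_error(train_embeddings(list()), "empty corpus")
})

test_that("co-occurring words score higher cosine than never-co-occurring", {
  corpus <- rep(list(c("druga", "conda"), c("noisez", "unrelated")), 40)
  tab <- train_embeddings(corpus, d = 16, min_count = 2, seed = 2)
  v <- tab$vectors
  expect_gt(cosine_similarity(v["druga", ], v["conda", ]),
            cosine_similarity(v["druga", ], v["noisez", ]))
})

test_that("cosine similarity obeys its contract", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(2, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_equal(cosine_similarity(c(1, 2), c(1, 2)), 1)
  expect_error(cosine_similarity(c(1, 0), c(0, 0)), "zero vector")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("negative-similarity filter drops exactly the negative mentions", {
  vecs <- rbind(drugx = c(1, 0), badconcept = c(-1, 0.1),
                goodconcept = c(1, 0.2))
  tab <- structure(list(vectors = vecs, meta = list(d = 2)),
                   class = "embedding_table")
  mentions <- rbind(
    mention_row("p", 0L, 0L, 1L, "good", "indication", "goodconcept"),
    mention_row("p", 0L, 2L, 3L, "bad", "indication", "badconcept"),
    mention_row("p", 0L, 4L, 5L, "new", "indication", "unseenconcept"))
  kept <- filter_nonmedical("drugx", mentions, tab)
  # cosine(drug, bad) = -1/sqrt(1.01) < 0 -> dropped; unseen concept retained
  expect_equal(kept$concept_id, c("goodconcept", "unseenconcept"))
  # output is an order-preserving subset of the input
  expect_true(all(kept$concept_id %in% mentions$concept_id))
  # identical vector is retained (cosine 1 >= 0)
  same <- mention_row("p", 0L, 0L, 1L, "drugx", "indication", "drugx")
  expect_equal(nrow(filter_nonmedical("drugx", same, tab)), 1L)
  expect_error(filter_nonmedical("absent", mentions, tab), "not in embedding")
})
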