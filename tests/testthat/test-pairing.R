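test_that("the bundled parser produces the expected fixture tree", {
  p <- parse_dependencies("I take gabapentin for pain")
  expect_s3_class(p, "parsed_sentence")
  expect_equal(p$tokens$surface, c("i", "take", "gabapentin", "for", "pain"))
  expect_equal(p$tokens$head_index, c(2L, 0L, 2L, 2L, 4L))
  # one-token sentence: the token is the root, zero edges
  p1 <- parse_dependencies("gabapentin")
  expect_equal(p1$tokens$head_index, 0L)
  expect_error(parse_dependencies(""), "empty sentence")
})

test_that("parsed_sentence enforces tree invariants", {
  expect_error(parsed_sentence(c("a", "b"), c(2L, 1L)), "root")
  expect_error(parsed_sentence(c("a", "b", "c"), c(0L, 3L, 2L)), "cyclic")
  expect_error(parsed_sentence(c("a", "b"), c(0L, 5L)), "out of range")
  expect_error(parsed_sentence(c("a", "b"), c(0L, 0L)), "exactly one root")
  # arbitrary random parses satisfy n - 1 edges and connectivity
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    p <- random_tree_sentence(n)
    expect_equal(sum(p$tokens$head_index != 0L), n - 1L)
  }
})

test_that("token graph has one component per sentence and tree edge counts", {
  p <- parse_dependencies("I take gabapentin for pain")
  g <- build_token_graph(p)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  expect_equal(igraph::degree(g, "s0_t2"), c(s0_t2 = 3))  # root "take"
  q <- parse_dependencies("It works for my insomnia", sentence_index = 1L)
  g2 <- build_token_graph(list(p, q))
  expect_equal(igraph::components(g2)$no, 2)
})

test_that("jump distance matches its definition on fixtures", {
  p <- parse_dependencies("I take gabapentin for pain")
  g <- build_token_graph(p)
  expect_equal(jump_distance(g, "s0_t3", "s0_t3"), 0)
  expect_equal(jump_distance(g, "s0_t3", "s0_t5"), 3)  # gabapentin-take-for-pain
  q <- parse_dependencies("It works for my insomnia", sentence_index = 1L)
  g2 <- build_token_graph(list(p, q))
  expect_equal(jump_distance(g2, "s0_t3", "s1_t5"), Inf)
  expect_error(jump_distance(g, "s9_t9", "s0_t1"), "not in graph")
})

test_that("jump distance agrees with a BFS oracle on random trees", {
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    p <- random_tree_sentence(n)
    g <- build_token_graph(p)
    pair <- sample.int(n, 2)
    d_pkg <- jump_distance(g, offlabelr:::token_node(0L, pair[1]),
                           offlabelr:::token_node(0L, pair[2]))
    d_bfs <- bfs_distance(n, edges_of(p), pair[1], pair[2])
    expect_equal(d_pkg, d_bfs)
    # symmetry
    expect_equal(d_pkg, jump_distance(g, offlabelr:::token_node(0L, pair[2]),
                                      offlabelr:::token_node(0L, pair[1])))
  }
})

test_that("cross-sentence substitution links adjacent sentences only", {
  parsed <- parse_post("My doctor prescribed quetiapine. It works for my insomnia.")
  drug <- mention_row("p", 0L, 3L, 4L, "quetiapine", "drug", "quetiapine")
  ind <- mention_row("p", 1L, 4L, 5L, "insomnia", "indication",
                     "sleep_disorder_insomnia")
  res <- resolve_cross_sentence(parsed, drug, ind)
  expect_false(is.null(res))
  expect_equal(res$jump_distance, 3)  # it-works-for-insomnia
  expect_false(res$negated)
  expect_equal(res$substitute_index, 1L)

  # adjacent sentence without a substitute word -> no pair
  parsed2 <- parse_post("My doctor prescribed quetiapine. Insomnia was awful.")
  ind2 <- mention_row("p", 1L, 0L, 1L, "insomnia", "indication",
                      "sleep_disorder_insomnia")
  expect_null(resolve_cross_sentence(parsed2, drug, ind2))

  # indication two sentences away exceeds the window
  parsed3 <- parse_post(
    "My doctor prescribed quetiapine. The visit was long. It works for my insomnia.")
  ind3 <- mention_row("p", 2L, 4L, 5L, "insomnia", "indication",
                      "sleep_disorder_insomnia")
  expect_null(resolve_cross_sentence(parsed3, drug, ind3))
})

test_that("negation is scoped to the dependency path and its dependents", {
  p <- parse_dependencies("I was not given quetiapine for anxiety")
  drug_idx <- which(p$tokens$surface == "quetiapine")
  ind_idx <- which(p$tokens$surface == "anxiety")
  expect_true(detect_negation(p, drug_idx, ind_idx))

  q <- parse_dependencies("I was given quetiapine for anxiety")
  expect_false(detect_negation(q, which(q$tokens$surface == "quetiapine"),
                               which(q$tokens$surface == "anxiety")))
})

test_that("extract_pairs applies the inclusive 9-jump threshold", {
  post <- data.frame(post_id = "p", drug_keyword = "gabapentin",
                     stringsAsFactors = FALSE)
  # planted fixture at distance 3
  parsed <- parse_post("I take gabapentin for pain")
  mentions <- rbind(
    mention_row("p", 0L, 2L, 3L, "gabapentin", "drug", "gabapentin"),
    mention_row("p", 0L, 4L, 5L, "pain", "indication", "pain"))
  pairs <- extract_pairs(post, mentions, parsed)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$jump_distance, 3L)
  expect_true(pairs$same_sentence)
  expect_false(pairs$negated)

  # constructed path fixtures at the boundary: 9 retained, 10 dropped
  for (n_edges in c(9L, 10L)) {
    sent <- path_sentence(n_edges)
    n_tok <- n_edges + 1L
    mentions <- rbind(
      mention_row("p", 0L, 0L, 1L, "gabapentin", "drug", "gabapentin"),
      mention_row("p", 0L, n_tok - 1L, n_tok, "pain", "indication", "pain"))
    # BFS oracle confirms the intended distance
    expect_equal(bfs_distance(n_tok, edges_of(sent), 1L, n_tok), n_edges)
    pairs <- extract_pairs(post, mentions, list(sent))
    expect_equal(nrow(pairs), if (n_edges <= 9L) 1L else 0L)
  }

  # no indication mention -> no pairs
  pairs <- extract_pairs(post, mentions[1, ], parse_post("I take gabapentin"))
  expect_equal(nrow(pairs), 0L)
})

test_that("pair retention is monotone in the jump threshold", {
  post <- data.frame(post_id = "p", drug_keyword = "gabapentin",
                     stringsAsFactors = FALSE)
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    sent <- random_tree_sentence(n)
    sent$tokens$surface[1] <- "gabapentin"
    sent$tokens$surface[n] <- "pain"
    mentions <- rbind(
      mention_row("p", 0L, 0L, 1L, "gabapentin", "drug", "gabapentin"),
      mention_row("p", 0L, n - 1L, n, "pain", "indication", "pain"))
    lo <- extract_pairs(post, mentions, list(sent),
                        pairing_config(max_jumps = 3L))
    hi <- extract_pairs(post, mentions, list(sent),
                        pairing_config(max_jumps = 12L))
    expect_gte(nrow(hi), nrow(lo))
  }
})

test_that("multi-token mentions anchor distance at their head token", {
  post <- data.frame(post_id = "p", drug_keyword = "gabapentin",
                     stringsAsFactors = FALSE)
  parsed <- parse_post("I take gabapentin for nerve pain")
  mentions <- rbind(
    mention_row("p", 0L, 2L, 3L, "gabapentin", "drug", "gabapentin"),
    mention_row("p", 0L, 4L, 6L, "nerve pain", "indication",
                "neuropathic_pain"))
  pairs <- extract_pairs(post, mentions, parsed)
  # head of "nerve pain" is "pain" (head outside the span): same distance as
  # the single-token mention
  expect_equal(pairs$jump_distance, 3L)
})

test_that("CoNLL-U fixture format round-trips", {
  p <- parse_dependencies("I take gabapentin for pain")
  q <- parse_dependencies("It works for my insomnia", sentence_index = 1L)
  lines <- format_conllu(list(p, q))
  back <- read_conllu(lines)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$tokens$surface, p$tokens$surface)
  expect_equal(back[[2]]$tokens$head_index, q$tokens$head_index)
})
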