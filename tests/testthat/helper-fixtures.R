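# Shared fixtures and independent oracles for the test suite.

fixture_lexicon <- function() read_lexicon()
fixture_label_map <- function() load_label_map()

# Independent breadth-first-search distance oracle over an edge list.
# Deliberately avoids igraph: plain queue over an adjacency list.
bfs_distance <- function(n_nodes, edges, from, to) {
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- rep(Inf, n_nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist[to]
}

# Random recursive tree as a parsed sentence: node i > 1 gets a uniformly
# random earlier node as head; node 1 is the root.
random_tree_sentence <- function(n, sentence_index = 0L) {
  heads <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  parsed_sentence(paste0("w", seq_len(n)), heads,
                  sentence_index = sentence_index)
}

edges_of <- function(parsed) {
  dep <- parsed$tokens[parsed$tokens$head_index != 0L, , drop = FALSE]
  cbind(dep$index, dep$head_index)
}

# A path-graph sentence with n_edges edges (token i hangs off token i - 1),
# used for jump-threshold boundary fixtures.
path_sentence <- function(n_edges, sentence_index = 0L) {
  n <- n_edges + 1L
  parsed_sentence(c("gabapentin", paste0("w", seq_len(n - 2L)), "pain"),
                  c(0L, seq_len(n - 1L)), sentence_index = sentence_index)
}

# One-row mention data.frame for hand-built pairing fixtures.
mention_row <- function(post_id, sentence_index, start, end, surface,
                        category, concept_id) {
  data.frame(post_id = post_id, sentence_index = sentence_index,
             start = start, end = end, surface = surface,
             category = category, concept_id = concept_id,
             stringsAsFactors = FALSE)
}

# Small synthetic corpus shared across relevance tests.
separable_corpus <- function(n = 200L, seed = 11L) {
  corp <- generate_synthetic_corpus(
    generator_config(n, seed = seed),
    fixture_lexicon(), fixture_label_map())
  list(texts = corp$posts$text, labels = corp$truth$relevant, corpus = corp)
}
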