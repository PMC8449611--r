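# Medical entity recognition by dictionary longest-match over the bundled
# lexicon, plus an embedding-based filter that removes candidate indications
# whose cosine similarity to the target drug is negative.

#' Split text into sentences
#'
#' Deterministic rule: a sentence ends at a run of `.`, `!` or `?` followed by
#' whitespace (or end of text). Returns the sentences with terminators
#' attached; empty input gives an empty vector.
#'
#' @param text Character scalar.
#' @return Character vector of sentences.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(character())
  parts <- unlist(strsplit(text, "(?<=[.!?])\\s+(?=[A-Z])", perl = TRUE),
                  use.names = FALSE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Recognize drug and indication mentions
#'
#' Greedy longest-match of lexicon surfaces over lowercase tokens, sentence by
#' sentence. Retained mention spans are pairwise non-overlapping; a longer
#' surface ("nerve pain") wins over a contained shorter one ("pain").
#'
#' @param text Spell-normalized post text.
#' @param lexicon [read_lexicon()] result.
#' @param post_id Optional post identifier copied onto each mention.
#' @return data.frame with columns \code{post_id}, \code{sentence_index}
#'   (0-based), \code{start}, \code{end} (half-open token interval within the
#'   sentence), \code{surface}, \code{category}, \code{concept_id}.
#' @export
recognize_entities <- function(text, lexicon, post_id = NA_character_) {
  stopifnot(inherits(lexicon, "ohc_lexicon"))
  empty <- data.frame(post_id = character(), sentence_index = integer(),
                      start = integer(), end = integer(),
                      surface = character(), category = character(),
                      concept_id = character(), stringsAsFactors = FALSE)
  sentences <- split_sentences(text)
  if (!length(sentences)) return(empty)
  entries <- lexicon$entries
  # index surfaces by their first token for fast lookup
  first_tok <- vapply(entries$surface, function(s) tokenize(s)[1L], character(1))
  surf_tokens <- lapply(entries$surface, tokenize)
  by_first <- split(seq_len(nrow(entries)), first_tok)
  out <- list()
  for (si in seq_along(sentences)) {
    toks <- tokenize(sentences[[si]])
    i <- 1L
    while (i <= length(toks)) {
      cand <- by_first[[toks[[i]]]]
      best <- NULL
      if (!is.null(cand)) {
        for (j in cand) {
          st <- surf_tokens[[j]]
          k <- length(st)
          if (i + k - 1L <= length(toks) &&
              identical(toks[i:(i + k - 1L)], st)) {
            if (is.null(best) || k > length(surf_tokens[[best]])) best <- j
          }
        }
      }
      if (!is.null(best)) {
        k <- length(surf_tokens[[best]])
        out[[length(out) + 1L]] <- data.frame(
          post_id = post_id, sentence_index = si - 1L,
          start = i - 1L, end = i - 1L + k,
          surface = entries$surface[[best]],
          category = entries$category[[best]],
          concept_id = entries$concept_id[[best]],
          stringsAsFactors = FALSE)
        i <- i + k
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Train word embeddings (skip-gram with negative sampling)
#'
#' A word2vec-style skip-gram model with negative sampling, trained by
#' mini-batch stochastic gradient descent, single-threaded and seeded so that
#' training is fully deterministic. Words that co-occur within the window are
#' pushed toward positive cosine similarity; words that never co-occur are
#' pushed apart, which is what the downstream negative-similarity filter
#' relies on.
#'
#' @param corpus List of character vectors (token lists), non-empty.
#' @param d Embedding dimension.
#' @param window Symmetric context window in tokens.
#' @param min_count Minimum corpus frequency for a token to receive a vector.
#' @param epochs Passes over the (center, context) pairs.
#' @param negative Negative samples per positive pair.
#' @param learning_rate Initial SGD step size (linearly decayed).
#' @param seed Integer seed for initialization, shuffling and sampling.
#' @return Object of class \code{embedding_table}: list with \code{vectors}
#'   (matrix, one named row per token) and \code{meta}.
#' @export
train_embeddings <- function(corpus, d = 100L, window = 5L, min_count = 2L,
                             epochs = 5L, negative = 5L,
                             learning_rate = 0.05, seed = 1L) {
  if (!length(corpus)) stop("empty corpus")
  counts <- table(unlist(corpus, use.names = FALSE))
  vocab <- sort(names(counts)[counts >= min_count])
  if (!length(vocab)) stop("no token reaches min_count = ", min_count)
  vidx <- stats::setNames(seq_along(vocab), vocab)
  nv <- length(vocab)
  d <- as.integer(d)
  # (center, context) pairs within the symmetric window
  centers <- integer(0); contexts <- integer(0)
  for (doc in corpus) {
    ids <- unname(vidx[doc])
    ids <- ids[!is.na(ids)]
    n <- length(ids)
    if (n < 2L) next
    for (off in seq_len(min(window, n - 1L))) {
      a <- ids[seq_len(n - off)]
      b <- ids[(1L + off):n]
      centers <- c(centers, a, b)
      contexts <- c(contexts, b, a)
    }
  }
  if (!length(centers)) stop("no co-occurrences within the window")
  # unigram^(3/4) negative-sampling distribution
  freq <- as.numeric(counts[vocab])^0.75
  neg_prob <- freq / sum(freq)
  sigmoid <- function(z) 1 / (1 + exp(-z))
  with_seed(seed, {
    W <- matrix(stats::runif(nv * d, -0.5, 0.5) / d, nv, d)
    C <- matrix(0, nv, d)
    n_pairs <- length(centers)
    chunk <- 512L
    total_steps <- as.integer(epochs) * n_pairs
    step <- 0L
    for (ep in seq_len(as.integer(epochs))) {
      ord <- sample.int(n_pairs)
      starts <- seq(1L, n_pairs, by = chunk)
      for (s in starts) {
        sel <- ord[s:min(s + chunk - 1L, n_pairs)]
        m <- length(sel)
        lr <- learning_rate * max(1e-4, 1 - step / total_steps)
        step <- step + m
        ctr <- centers[sel]; pos <- contexts[sel]
        neg <- matrix(sample.int(nv, m * negative, replace = TRUE,
                                 prob = neg_prob), m, negative)
        w <- W[ctr, , drop = FALSE]
        cpos <- C[pos, , drop = FALSE]
        gpos <- sigmoid(rowSums(w * cpos)) - 1      # label 1
        gw <- gpos * cpos
        gc_pos <- gpos * w
        for (k in seq_len(negative)) {
          cneg <- C[neg[, k], , drop = FALSE]
          gneg <- sigmoid(rowSums(w * cneg))         # label 0
          gw <- gw + gneg * cneg
          upd <- rowsum(gneg * w, neg[, k])
          rid <- as.integer(rownames(upd))
          C[rid, ] <- C[rid, , drop = FALSE] - lr * upd
        }
        updW <- rowsum(gw, ctr)
        rid <- as.integer(rownames(updW))
        W[rid, ] <- W[rid, , drop = FALSE] - lr * updW
        updC <- rowsum(gc_pos, pos)
        rid <- as.integer(rownames(updC))
        C[rid, ] <- C[rid, , drop = FALSE] - lr * updC
      }
    }
    rownames(W) <- vocab
    W <- W[sqrt(rowSums(W^2)) > 1e-12, , drop = FALSE]
    structure(list(vectors = W,
                   meta = list(d = d, window = as.integer(window),
                               min_count = as.integer(min_count),
                               epochs = as.integer(epochs),
                               negative = as.integer(negative),
                               seed = as.integer(seed))),
              class = "embedding_table")
  })
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x$vectors), " tokens, dimension ",
      x$meta$d, "\n", sep = "")
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal dimension and nonzero norm.
#' @return Value in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector has no cosine similarity")
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Filter out non-medical candidate mentions by embedding similarity
#'
#' A mention is removed iff its concept has a vector and the cosine
#' similarity between the target drug vector and the mention vector is below
#' the threshold (default 0: the negative-similarity sign test). Mentions
#' without a vector are retained.
#'
#' @param drug_concept Concept id of the target drug; must be in the table.
#' @param mentions Mention data.frame from [recognize_entities()].
#' @param table [train_embeddings()] result.
#' @param threshold Similarity threshold; similarity strictly below it drops
#'   the mention.
#' @return The retained subset of \code{mentions}, order preserved.
#' @export
filter_nonmedical <- function(drug_concept, mentions, table, threshold = 0) {
  stopifnot(inherits(table, "embedding_table"))
  if (!(drug_concept %in% rownames(table$vectors))) {
    stop("drug concept not in embedding vocabulary: ", drug_concept)
  }
  if (!nrow(mentions)) return(mentions)
  dv <- table$vectors[drug_concept, ]
  keep <- vapply(seq_len(nrow(mentions)), function(i) {
    key <- mentions$concept_id[[i]]
    if (!(key %in% rownames(table$vectors))) return(TRUE)
    cosine_similarity(dv, table$vectors[key, ]) >= threshold
  }, logical(1))
  mentions[keep, , drop = FALSE]
}
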