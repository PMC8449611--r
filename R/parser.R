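# Dependency parsing interface. Any backend producing a valid ParsedSentence
# (one root, heads forming a tree) can drive the pairing stage; the package
# bundles a deterministic rule-based parser adequate for the short,
# template-like sentences of consumer forum posts and for test fixtures.

.parser_verbs <- c(
  "take", "takes", "took", "taken", "taking", "prescribe", "prescribed",
  "prescribes", "give", "gives", "gave", "given", "work", "works", "worked",
  "help", "helps", "helped", "use", "uses", "used", "using", "start",
  "started", "starting", "try", "tried", "tries", "put", "treat", "treats",
  "treated", "manage", "managed", "manages", "recommend", "recommended",
  "suggest", "suggested", "switched", "stopped", "know", "discussed",
  "looking", "wondering", "is", "was", "are", "were", "am", "be", "been")

.parser_aux <- c("is", "was", "are", "were", "am", "be", "been", "being",
                 "do", "does", "did", "have", "has", "had", "will", "would",
                 "can", "could", "should", "may", "might", "must")

.parser_preps <- c("for", "with", "to", "of", "on", "in", "at", "from",
                   "about", "against", "after", "before", "during", "as",
                   "if", "over", "under")

.parser_dets <- c("a", "an", "the", "my", "your", "his", "her", "their",
                  "our", "its", "this", "that", "these", "those", "some",
                  "any", "last", "every")

.parser_negs <- c("not", "never", "no", "n't", "without")

#' Construct a parsed sentence
#'
#' Validates the dependency-tree invariants: exactly one root (head 0), all
#' heads inside the sentence, and the (token, head) edges forming a single
#' connected acyclic tree.
#'
#' @param tokens Character vector of token surfaces.
#' @param heads Integer vector: 1-based head index per token, 0 for the root.
#' @param labels Optional dependency labels (default "dep"/"root").
#' @param sentence_index 0-based sentence position within the post.
#' @return Object of class \code{parsed_sentence}.
#' @export
parsed_sentence <- function(tokens, heads, labels = NULL, sentence_index = 0L) {
  n <- length(tokens)
  heads <- as.integer(heads)
  if (length(heads) != n) stop("tokens and heads differ in length")
  if (n == 0L) stop("empty sentence")
  if (sum(heads == 0L) != 1L) stop("dependency tree must have exactly one root")
  if (any(heads < 0L | heads > n)) stop("head index out of range")
  if (any(heads == seq_len(n))) stop("token cannot head itself")
  # connectivity/acyclicity: every token must reach the root
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (heads[[j]] != 0L) {
      if (seen[[j]]) stop("cyclic head assignment at token ", i)
      seen[[j]] <- TRUE
      j <- heads[[j]]
    }
  }
  if (is.null(labels)) labels <- ifelse(heads == 0L, "root", "dep")
  structure(list(sentence_index = as.integer(sentence_index),
                 tokens = data.frame(index = seq_len(n), surface = tokens,
                                     head_index = heads, label = labels,
                                     stringsAsFactors = FALSE)),
            class = "parsed_sentence")
}

#' @export
print.parsed_sentence <- function(x, ...) {
  cat("<parsed_sentence #", x$sentence_index, "> ",
      paste(x$tokens$surface, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Format parsed sentences as CoNLL-U-style TSV
#'
#' @param parsed A \code{parsed_sentence} or list of them.
#' @return Character vector of TSV lines (index, surface, head, label).
#' @export
format_conllu <- function(parsed) {
  if (inherits(parsed, "parsed_sentence")) parsed <- list(parsed)
  unlist(lapply(parsed, function(p) {
    c(sprintf("%d\t%s\t%d\t%s", p$tokens$index, p$tokens$surface,
              p$tokens$head_index, p$tokens$label), "")
  }), use.names = FALSE)
}

#' Read parsed sentences from CoNLL-U-style TSV lines
#'
#' @param lines Character vector; sentences separated by blank lines.
#' @return List of \code{parsed_sentence}.
#' @export
read_conllu <- function(lines) {
  groups <- split(lines, cumsum(!nzchar(trimws(lines))))
  groups <- lapply(groups, function(g) g[nzchar(trimws(g))])
  groups <- groups[lengths(groups) > 0L]
  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    f <- strsplit(groups[[k]], "\t", fixed = TRUE)
    out[[k]] <- parsed_sentence(
      tokens = vapply(f, `[[`, character(1), 2L),
      heads = as.integer(vapply(f, `[[`, character(1), 3L)),
      labels = vapply(f, `[[`, character(1), 4L),
      sentence_index = k - 1L)
  }
  out
}

#' Parse a sentence with the bundled rule-based parser
#'
#' A deterministic head-assignment parser: the last verb becomes the root;
#' auxiliaries and negation cues attach to the root; prepositions attach to
#' the root; determiners attach to the following content token; contiguous
#' content-word runs attach their non-final tokens to the run's final token
#' (noun-compound convention), and the run head attaches to an immediately
#' preceding unsaturated preposition, else to the root.
#'
#' @param sentence_text Non-empty sentence string.
#' @param sentence_index 0-based sentence position.
#' @return \code{parsed_sentence}.
#' @export
parse_dependencies <- function(sentence_text, sentence_index = 0L) {
  toks <- tokenize(sentence_text)
  if (!length(toks)) stop("cannot parse an empty sentence: ",
                          deparse(sentence_text))
  n <- length(toks)
  kind <- rep("content", n)
  kind[toks %in% .parser_preps] <- "prep"
  kind[toks %in% .parser_dets] <- "det"
  kind[toks %in% .parser_negs] <- "neg"
  verb_pos <- which(toks %in% .parser_verbs)
  root <- if (length(verb_pos)) max(verb_pos) else 1L
  kind[root] <- "root"
  kind[setdiff(which(toks %in% .parser_aux), root)] <- "aux"
  # question words stay content; single-token sentence
  heads <- integer(n)
  labels <- character(n)
  heads[root] <- 0L; labels[root] <- "root"
  # content runs (maximal stretches of consecutive "content" tokens)
  i <- 1L
  while (i <= n) {
    if (kind[[i]] == "content") {
      j <- i
      while (j < n && kind[[j + 1L]] == "content") j <- j + 1L
      head_tok <- j
      if (i < j) {
        heads[i:(j - 1L)] <- head_tok
        labels[i:(j - 1L)] <- "compound"
      }
      # attach run head: preceding preposition (skipping determiners), else root
      k <- i - 1L
      while (k >= 1L && kind[[k]] == "det") k <- k - 1L
      if (k >= 1L && kind[[k]] == "prep") {
        heads[head_tok] <- k; labels[head_tok] <- "pobj"
      } else {
        heads[head_tok] <- root
        labels[head_tok] <- if (head_tok < root) "nsubj" else "obj"
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  for (i in seq_len(n)) {
    if (i == root) next
    switch(kind[[i]],
      prep = { heads[i] <- root; labels[i] <- "prep" },
      aux = { heads[i] <- root; labels[i] <- "aux" },
      neg = { heads[i] <- root; labels[i] <- "neg" },
      det = {
        # following content token, else root
        nxt <- which(kind == "content" & seq_len(n) > i)
        if (length(nxt)) { heads[i] <- min(nxt); labels[i] <- "det" }
        else { heads[i] <- root; labels[i] <- "det" }
      },
      NULL)
  }
  parsed_sentence(toks, heads, labels, sentence_index)
}

#' Parse every sentence of a post
#'
#' @param text Post text (spell-normalized).
#' @param parser A function \code{(sentence_text, sentence_index) ->
#'   parsed_sentence}; defaults to the bundled rule-based parser.
#' @return List of \code{parsed_sentence}, one per sentence.
#' @export
parse_post <- function(text, parser = parse_dependencies) {
  sentences <- split_sentences(text)
  lapply(seq_along(sentences), function(i) {
    p <- parser(sentences[[i]], i - 1L)
    if (!inherits(p, "parsed_sentence")) {
      p <- parsed_sentence(p$tokens$surface, p$tokens$head_index,
                           p$tokens$label, i - 1L)
    }
    p$sentence_index <- i - 1L
    p
  })
}
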