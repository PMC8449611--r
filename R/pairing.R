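# Drug–indication pairing over dependency graphs: shortest-path jump
# distance with an inclusive threshold (default 9 edges), a cross-sentence
# substitution rule for anaphoric drug references ("it", "drug",
# "medication") in adjacent sentences, and negation detection scoped to the
# dependency path between the pair.

#' Pairing configuration
#'
#' @param max_jumps Inclusive shortest-path threshold in dependency edges
#'   (default 9); pairs farther apart are dropped.
#' @param substitution_words Lowercase anaphora that may stand in for the
#'   drug in an adjacent sentence.
#' @param adjacent_window Sentences checked on each side for cross-sentence
#'   pairs.
#' @param negation_cues Lowercase cue tokens that negate a pair when they lie
#'   on, or hang directly off, the drug–indication dependency path.
#' @return List of class \code{pairing_config}.
#' @export
pairing_config <- function(max_jumps = 9L,
                           substitution_words = c("it", "drug", "medication"),
                           adjacent_window = 1L,
                           negation_cues = c("not", "never", "no", "without",
                                             "n't")) {
  if (max_jumps < 1L) stop("max_jumps must be >= 1")
  if (adjacent_window < 0L) stop("adjacent_window must be >= 0")
  structure(list(max_jumps = as.integer(max_jumps),
                 substitution_words = tolower(substitution_words),
                 adjacent_window = as.integer(adjacent_window),
                 negation_cues = tolower(negation_cues)),
            class = "pairing_config")
}

token_node <- function(sentence_index, token_index) {
  sprintf("s%d_t%d", sentence_index, token_index)
}

#' Build an undirected token graph from parsed sentences
#'
#' One node per token, one undirected edge per (token, head) dependency;
#' sentences form separate connected components.
#'
#' @param parsed List of \code{parsed_sentence} (or a single one).
#' @return An \pkg{igraph} graph with node names \code{s<sent>_t<index>}.
#' @export
build_token_graph <- function(parsed) {
  if (inherits(parsed, "parsed_sentence")) parsed <- list(parsed)
  nodes <- character(); edges <- character()
  for (p in parsed) {
    si <- p$sentence_index
    nodes <- c(nodes, token_node(si, p$tokens$index))
    dep <- p$tokens[p$tokens$head_index != 0L, , drop = FALSE]
    if (nrow(dep)) {
      edges <- c(edges, rbind(token_node(si, dep$index),
                              token_node(si, dep$head_index)))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Shortest-path jump distance between two tokens
#'
#' @param graph Token graph from [build_token_graph()].
#' @param a,b Node names (\code{s<sent>_t<index>}).
#' @return Number of edges on the shortest path; 0 iff \code{a == b};
#'   \code{Inf} when unreachable (different components).
#' @export
jump_distance <- function(graph, a, b) {
  vn <- igraph::V(graph)$name
  if (!(a %in% vn) || !(b %in% vn)) {
    stop("token not in graph: ", if (!(a %in% vn)) a else b)
  }
  as.numeric(igraph::distances(graph, v = a, to = b)[1L, 1L])
}

# Head token of a mention span: the span token whose head lies outside the
# span (1-based token index); falls back to the last span token.
mention_head_token <- function(parsed_sentence, start, end) {
  span <- (start + 1L):end
  heads <- parsed_sentence$tokens$head_index[span]
  outside <- span[!(heads %in% span)]
  if (length(outside)) outside[[1L]] else span[[length(span)]]
}

#' Detect negation on the dependency path between two tokens
#'
#' TRUE iff a negation cue token lies on the shortest dependency path between
#' the two tokens or is a direct dependent of a path token. Scoped to a
#' single (possibly rewritten) sentence.
#'
#' @param parsed A \code{parsed_sentence}.
#' @param a_index,b_index 1-based token indices within the sentence.
#' @param cfg [pairing_config()].
#' @return Logical scalar.
#' @export
detect_negation <- function(parsed, a_index, b_index, cfg = pairing_config()) {
  g <- build_token_graph(list(parsed))
  si <- parsed$sentence_index
  path <- igraph::shortest_paths(
    g, from = token_node(si, a_index), to = token_node(si, b_index),
    output = "vpath")$vpath[[1]]
  path_idx <- as.integer(sub(".*_t", "", names(path)))
  toks <- tolower(parsed$tokens$surface)
  cue_idx <- which(toks %in% cfg$negation_cues)
  if (!length(cue_idx)) return(FALSE)
  any(cue_idx %in% path_idx |
        parsed$tokens$head_index[cue_idx] %in% path_idx)
}

#' Resolve a cross-sentence drug–indication pair by anaphora substitution
#'
#' When drug and indication sit in different sentences within the adjacent
#' window, the indication's sentence is searched for a substitution word
#' ("it", "drug", "medication"); the first such token in reading order is
#' re-labeled as the drug and the jump distance is computed within the
#' rewritten sentence. Without a substitute word there is no pair.
#'
#' @param parsed List of \code{parsed_sentence} for the post.
#' @param drug_mention,indication_mention One-row mention data.frames
#'   (from [recognize_entities()]) in different sentences.
#' @param cfg [pairing_config()].
#' @return NULL if no pair can be formed; otherwise a list with
#'   \code{jump_distance}, \code{negated}, \code{substitute_index} and the
#'   \code{rewritten} sentence.
#' @export
resolve_cross_sentence <- function(parsed, drug_mention, indication_mention,
                                   cfg = pairing_config()) {
  ds <- drug_mention$sentence_index
  is_ <- indication_mention$sentence_index
  if (ds == is_) stop("mentions are in the same sentence")
  if (abs(ds - is_) > cfg$adjacent_window) return(NULL)
  sent <- NULL
  for (p in parsed) if (p$sentence_index == is_) sent <- p
  if (is.null(sent)) stop("indication sentence not found in parse list")
  span <- (indication_mention$start + 1L):indication_mention$end
  toks <- tolower(sent$tokens$surface)
  subs <- setdiff(which(toks %in% cfg$substitution_words), span)
  if (!length(subs)) return(NULL)
  sub_idx <- min(subs)
  rewritten <- sent
  rewritten$tokens$surface[sub_idx] <- drug_mention$surface
  ind_head <- mention_head_token(rewritten, indication_mention$start,
                                 indication_mention$end)
  g <- build_token_graph(list(rewritten))
  d <- jump_distance(g, token_node(is_, sub_idx), token_node(is_, ind_head))
  list(jump_distance = d,
       negated = detect_negation(rewritten, sub_idx, ind_head, cfg),
       substitute_index = sub_idx, rewritten = rewritten)
}

#' Extract candidate drug–indication pairs from a post
#'
#' Evaluates every (drug mention of the post's target drug, indication
#' mention) combination: same-sentence pairs by shortest dependency path,
#' cross-sentence pairs via [resolve_cross_sentence()]. Pairs whose jump
#' distance exceeds \code{cfg$max_jumps} are dropped (the threshold is
#' inclusive: distance 9 is retained under the default). Each retained pair
#' carries its negation flag.
#'
#' @param post One-row post data.frame (needs \code{post_id},
#'   \code{drug_keyword}).
#' @param mentions Mentions from [recognize_entities()] (post-filter).
#' @param parsed List of \code{parsed_sentence} from [parse_post()].
#' @param cfg [pairing_config()].
#' @return data.frame of pairs: \code{post_id}, \code{drug},
#'   \code{drug_surface}, \code{indication}, \code{indication_surface},
#'   \code{jump_distance}, \code{same_sentence}, \code{substitution_used},
#'   \code{negated}.
#' @export
extract_pairs <- function(post, mentions, parsed, cfg = pairing_config()) {
  empty <- data.frame(post_id = character(), drug = character(),
                      drug_surface = character(), indication = character(),
                      indication_surface = character(),
                      jump_distance = integer(), same_sentence = logical(),
                      substitution_used = logical(), negated = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(mentions)) return(empty)
  kw <- tolower(post$drug_keyword)
  drugs <- mentions[mentions$category == "drug" &
                      (mentions$concept_id == kw | mentions$surface == kw), ,
                    drop = FALSE]
  inds <- mentions[mentions$category == "indication", , drop = FALSE]
  if (!nrow(drugs) || !nrow(inds)) return(empty)
  sent_of <- function(si) {
    for (p in parsed) if (p$sentence_index == si) return(p)
    NULL
  }
  out <- list()
  for (i in seq_len(nrow(drugs))) {
    dm <- drugs[i, , drop = FALSE]
    for (j in seq_len(nrow(inds))) {
      im <- inds[j, , drop = FALSE]
      if (dm$sentence_index == im$sentence_index) {
        sent <- sent_of(dm$sentence_index)
        if (is.null(sent)) next
        dh <- mention_head_token(sent, dm$start, dm$end)
        ih <- mention_head_token(sent, im$start, im$end)
        g <- build_token_graph(list(sent))
        d <- jump_distance(g, token_node(sent$sentence_index, dh),
                           token_node(sent$sentence_index, ih))
        if (is.finite(d) && d <= cfg$max_jumps) {
          out[[length(out) + 1L]] <- data.frame(
            post_id = post$post_id, drug = dm$concept_id,
            drug_surface = dm$surface, indication = im$concept_id,
            indication_surface = im$surface, jump_distance = as.integer(d),
            same_sentence = TRUE, substitution_used = FALSE,
            negated = detect_negation(sent, dh, ih, cfg),
            stringsAsFactors = FALSE)
        }
      } else if (abs(dm$sentence_index - im$sentence_index) <=
                   cfg$adjacent_window) {
        res <- resolve_cross_sentence(parsed, dm, im, cfg)
        if (!is.null(res) && is.finite(res$jump_distance) &&
            res$jump_distance <= cfg$max_jumps) {
          out[[length(out) + 1L]] <- data.frame(
            post_id = post$post_id, drug = dm$concept_id,
            drug_surface = dm$surface, indication = im$concept_id,
            indication_surface = im$surface,
            jump_distance = as.integer(res$jump_distance),
            same_sentence = FALSE, substitution_used = TRUE,
            negated = res$negated, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
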