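# Consumer-language spelling normalization: a lexicon/edit-distance corrector
# standing behind the pipeline's spell-check stage. Matching is
# case-insensitive; corrections are emitted lowercase; tokens shorter than 4
# characters are never touched (protects "it", "rx", dosage tokens).

.spell_min_nchar <- 4L

# candidate vocabulary bucketed by token length for cheap pruning
build_spell_index <- function(lexicon) {
  med <- lexicon_medical_tokens(lexicon)
  vocab <- lexicon_token_vocabulary(lexicon)
  list(vocab = vocab, medical = med, len = nchar(vocab))
}

#' Correct a single token against the lexicon
#'
#' In-vocabulary tokens (medical lexicon surfaces or general vocabulary) are
#' returned unchanged. Otherwise the unique closest candidate within
#' \code{max_edit} Levenshtein edits is returned; ties prefer medical-lexicon
#' tokens over general vocabulary, then lexicographic order. With no candidate
#' the token is returned unchanged. The operation is idempotent.
#'
#' @param token Non-empty character scalar.
#' @param lexicon [read_lexicon()] result.
#' @param max_edit Maximum Levenshtein distance (default 2).
#' @return List with \code{token} (the corrected, lowercase if corrected,
#'   token) and \code{correction} (NULL, or a one-row data.frame with
#'   \code{original}, \code{corrected}, \code{edit_distance}).
#' @export
correct_token <- function(token, lexicon, max_edit = 2L) {
  stopifnot(is.character(token), length(token) == 1L, nzchar(token))
  idx <- if (inherits(lexicon, "spell_index")) lexicon else
    structure(build_spell_index(lexicon), class = "spell_index")
  low <- tolower(token)
  if (nchar(low) < .spell_min_nchar || low %in% idx$vocab) {
    return(list(token = token, correction = NULL))
  }
  keep <- abs(idx$len - nchar(low)) <= max_edit
  cands <- idx$vocab[keep]
  if (!length(cands)) return(list(token = token, correction = NULL))
  d <- utils::adist(low, cands)[1L, ]
  dmin <- min(d)
  if (dmin > max_edit) return(list(token = token, correction = NULL))
  best <- cands[d == dmin]
  med <- best[best %in% idx$medical]
  pick <- if (length(med)) sort(med)[1L] else sort(best)[1L]
  list(token = pick,
       correction = data.frame(original = low, corrected = pick,
                               edit_distance = as.integer(dmin),
                               stringsAsFactors = FALSE))
}

#' Spell-correct free text
#'
#' Applies [correct_token()] to every word token, preserving token count and
#' all non-token characters (punctuation, whitespace) verbatim. Applying the
#' function to its own output is a fixed point.
#'
#' @param text Character scalar.
#' @param lexicon [read_lexicon()] result (or a prebuilt index from
#'   [build_spell_index()]).
#' @param max_edit Maximum Levenshtein distance per token.
#' @return List with \code{text} (corrected) and \code{corrections}
#'   (data.frame with \code{original}, \code{corrected},
#'   \code{edit_distance}, \code{position} — 1-based token index).
#' @export
correct_text <- function(text, lexicon, max_edit = 2L) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(original = character(), corrected = character(),
                      edit_distance = integer(), position = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(list(text = text, corrections = empty))
  idx <- if (inherits(lexicon, "spell_index")) lexicon else
    structure(build_spell_index(lexicon), class = "spell_index")
  m <- gregexpr(.token_regex, text, perl = TRUE)
  toks <- regmatches(text, m)[[1]]
  if (!length(toks)) return(list(text = text, corrections = empty))
  corrections <- vector("list", length(toks))
  out <- toks
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(toks)) {
    key <- tolower(toks[[i]])
    if (is.null(cache[[key]])) {
      r <- correct_token(key, idx, max_edit)
      cache[[key]] <- if (is.null(r$correction)) list(corrected = NULL)
                      else list(corrected = r$token,
                                edit_distance = r$correction$edit_distance)
    }
    hit <- cache[[key]]
    if (!is.null(hit$corrected)) {
      out[[i]] <- hit$corrected
      corrections[[i]] <- data.frame(
        original = key, corrected = hit$corrected,
        edit_distance = hit$edit_distance, position = i,
        stringsAsFactors = FALSE)
    }
  }
  regmatches(text, m) <- list(out)
  corrections <- corrections[!vapply(corrections, is.null, logical(1))]
  list(text = text,
       corrections = if (length(corrections)) do.call(rbind, corrections)
                     else empty)
}
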