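#' @keywords internal
"_PACKAGE"

# Word-token regex shared by the tokenizer, the spelling corrector and the
# entity recognizer: runs of letters/digits with internal apostrophes.
.token_regex <- "[A-Za-z0-9]+(?:'[A-Za-z0-9]+)*"

#' Tokenize text into lowercase word tokens
#'
#' Lowercases and splits on non-alphanumeric characters (apostrophes are kept
#' inside tokens). This is the single tokenizer used by every stage so that
#' token indices agree across spelling correction, entity recognition and
#' dependency pairing.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr(.token_regex, text, perl = TRUE)
  toks <- regmatches(text, m)[[1]]
  tolower(toks)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic stages derive child seeds from one root seed via this helper.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed from a root seed and a stage label; keeps results
# of one stage independent of how many random draws another stage consumed.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 131L + as.integer(h %% 100003L)) %% 2147483587L
}

#' Bundled English stopword list
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "offlabelr")
  readLines(path, encoding = "UTF-8")
}
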