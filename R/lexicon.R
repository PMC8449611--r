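#' Read a medical lexicon
#'
#' The lexicon maps surface forms to concept identifiers in two categories,
#' \code{drug} and \code{indication}, and carries a general (non-medical)
#' vocabulary used by the spelling corrector. Multi-word surfaces are stored
#' token-split so the longest-match recognizer can walk them token by token.
#'
#' @param path TSV file with columns \code{surface}, \code{concept_id},
#'   \code{category}. Defaults to the bundled lexicon.
#' @param general_vocabulary_path One lowercase word per line; defaults to the
#'   bundled general English vocabulary.
#' @return An object of class \code{ohc_lexicon}: a list with \code{entries}
#'   (data.frame \code{surface}, \code{concept_id}, \code{category},
#'   \code{n_tokens}) and \code{general_vocabulary} (character vector).
#' @export
read_lexicon <- function(path = NULL, general_vocabulary_path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ohc_lexicon.tsv", package = "offlabelr")
  }
  if (is.null(general_vocabulary_path)) {
    general_vocabulary_path <-
      system.file("extdata", "general_vocabulary.txt", package = "offlabelr")
  }
  entries <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character")
  required <- c("surface", "concept_id", "category")
  if (!all(required %in% names(entries))) {
    stop("lexicon file must have columns surface, concept_id, category")
  }
  entries$surface <- tolower(trimws(entries$surface))
  if (any(!nzchar(entries$concept_id))) stop("empty concept_id in lexicon")
  bad <- setdiff(unique(entries$category), c("drug", "indication"))
  if (length(bad)) stop("unknown lexicon category: ", paste(bad, collapse = ", "))
  dup <- duplicated(entries[c("surface", "category")])
  if (any(dup)) {
    stop("duplicate lexicon surface within category: ",
         paste(unique(entries$surface[dup]), collapse = ", "))
  }
  entries$n_tokens <- lengths(lapply(entries$surface, tokenize))
  gv <- tolower(trimws(readLines(general_vocabulary_path, encoding = "UTF-8")))
  gv <- gv[nzchar(gv)]
  structure(list(entries = entries, general_vocabulary = unique(gv)),
            class = "ohc_lexicon")
}

#' @export
print.ohc_lexicon <- function(x, ...) {
  tab <- table(x$entries$category)
  cat("<ohc_lexicon> ", nrow(x$entries), " entries (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), "); ",
      length(x$general_vocabulary), " general vocabulary words\n", sep = "")
  invisible(x)
}

# All single tokens known to the corrector: lexicon surface tokens plus the
# general vocabulary.
lexicon_token_vocabulary <- function(lexicon) {
  surf_tokens <- unlist(lapply(lexicon$entries$surface, tokenize),
                        use.names = FALSE)
  unique(c(surf_tokens, lexicon$general_vocabulary))
}

# Tokens that occur in medical surfaces (used by the corrector's tie-break).
lexicon_medical_tokens <- function(lexicon) {
  unique(unlist(lapply(lexicon$entries$surface, tokenize), use.names = FALSE))
}

lexicon_drugs <- function(lexicon) {
  unique(lexicon$entries$concept_id[lexicon$entries$category == "drug"])
}

lexicon_indications <- function(lexicon) {
  unique(lexicon$entries$concept_id[lexicon$entries$category == "indication"])
}
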