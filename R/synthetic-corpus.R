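# Synthetic OHC corpus generator. Emulates keyword-scraped patient-forum
# posts with planted ground truth so the pipeline can be evaluated without a
# deposited corpus. Post templates cover the taxonomy that distinguishes
# relevant from irrelevant posts: firsthand or family/friend drug experience
# versus general knowledge and consumption-free questions.

.relevant_templates_plain <- c(
  "I take {drug} for {indication}.",
  "I have been taking {drug} for my {indication}.",
  "My doctor prescribed {drug} for my {indication}.",
  "My mother takes {drug} for her {indication}.",
  "The doctor put me on {drug} for {indication}.")

.relevant_templates_negated <- c(
  "I was not given {drug} for {indication}.",
  "I do not take {drug} for my {indication}.")

.relevant_templates_cross <- c(
  "My doctor prescribed {drug}. It helps with my {indication}.",
  "I started {drug} last month. This medication works for my {indication}.")

.irrelevant_templates <- c(
  "What is the usual dose of {drug}?",
  "Does anyone know if {drug} is available as generic?",
  "{drug} is widely discussed in many articles.",
  "Looking for general information about {drug}.",
  "Is {drug} the same as the generic version?")

.ambiguous_suffix <- " I am not sure if it was for that."

.ohc_sources <- c("medhelp", "webmd", "drugs.com", "healthboards")

#' Configuration for the synthetic corpus generator
#'
#' Defaults encode the study conditions the pipeline is evaluated under:
#' 70% relevant posts (the 7000/3000 annotation split), roughly one in five
#' relevant posts describing an off-label use (matching the ~18.6% off-label
#' share observed downstream), and modest rates of misspelling, negation and
#' cross-sentence mention separation.
#'
#' @param n_posts Number of posts to generate (>= 0).
#' @param frac_relevant Proportion of relevant (patient-experience) posts.
#' @param frac_off_label Proportion of relevant pairable posts whose planted
#'   indication is not FDA-approved for the drug.
#' @param misspell_rate Proportion of posts receiving one injected
#'   single-character misspelling (never in the first character, always
#'   recoverable at edit distance <= 2).
#' @param negation_rate Proportion of relevant posts with a negated pair.
#' @param cross_sentence_rate Proportion of (non-negated) relevant posts whose
#'   drug and indication sit in adjacent sentences linked by a substitution
#'   word.
#' @param ambiguous_rate Proportion of relevant posts marked ambiguous (a
#'   hedging sentence is appended; excluded from dataset-B style scoring).
#' @param seed Integer root seed; fixed seed gives a byte-identical corpus.
#' @return List of class \code{generator_config}.
#' @export
generator_config <- function(n_posts, frac_relevant = 0.7,
                             frac_off_label = 0.2, misspell_rate = 0.1,
                             negation_rate = 0.1, cross_sentence_rate = 0.15,
                             ambiguous_rate = 0, seed = 1L) {
  props <- c(frac_relevant = frac_relevant, frac_off_label = frac_off_label,
             misspell_rate = misspell_rate, negation_rate = negation_rate,
             cross_sentence_rate = cross_sentence_rate,
             ambiguous_rate = ambiguous_rate)
  if (any(props < 0 | props > 1)) {
    stop("all generator proportions must lie in [0, 1]")
  }
  if (length(n_posts) != 1L || is.na(n_posts) || n_posts < 0) {
    stop("n_posts must be a single non-negative integer")
  }
  structure(c(list(n_posts = as.integer(n_posts)), as.list(props),
              list(seed = as.integer(seed))),
            class = "generator_config")
}

# First lexicon surface for each indication concept (deterministic choice).
concept_surfaces <- function(lexicon) {
  ind <- lexicon$entries[lexicon$entries$category == "indication", ]
  ind <- ind[!duplicated(ind$concept_id), ]
  stats::setNames(ind$surface, ind$concept_id)
}

corrupt_token <- function(token) {
  # one substitution or deletion, never at the first character
  n <- nchar(token)
  pos <- sample(2:n, 1L)
  if (stats::runif(1) < 0.5 && n > 4L) {
    paste0(substr(token, 1L, pos - 1L), substr(token, pos + 1L, n))
  } else {
    ch <- substr(token, pos, pos)
    repl <- sample(setdiff(letters, ch), 1L)
    paste0(substr(token, 1L, pos - 1L), repl, substr(token, pos + 1L, n))
  }
}

#' Generate a synthetic annotated OHC corpus
#'
#' Produces keyword-scraped-style posts over the bundled 12-drug list with a
#' ground-truth sidecar: relevance, the planted drug–indication pair, its
#' negation/cross-sentence status, and the off-label truth derived from the
#' label map. A fixed seed yields a byte-identical corpus.
#'
#' @param config [generator_config()].
#' @param lexicon [read_lexicon()] result; must contain at least one drug and,
#'   per drug, at least one approved and one non-approved indication surface.
#' @param label_map [load_label_map()] result.
#' @return List with \code{posts} (data.frame) and \code{truth} (data.frame
#'   with list-column \code{planted_pairs}).
#' @export
generate_synthetic_corpus <- function(config, lexicon, label_map) {
  stopifnot(inherits(config, "generator_config"),
            inherits(lexicon, "ohc_lexicon"),
            inherits(label_map, "label_map"))
  drugs <- intersect(lexicon_drugs(lexicon), names(label_map$approved))
  if (!length(drugs)) stop("lexicon and label map share no drugs")
  surfaces <- concept_surfaces(lexicon)
  all_concepts <- names(surfaces)
  on_pool <- lapply(stats::setNames(drugs, drugs), function(d)
    intersect(label_map$approved[[d]], all_concepts))
  off_pool <- lapply(stats::setNames(drugs, drugs), function(d)
    setdiff(all_concepts, label_map$approved[[d]]))
  if (any(!lengths(on_pool))) {
    stop("no approved indication with a lexicon surface for: ",
         paste(drugs[!lengths(on_pool)], collapse = ", "))
  }
  if (config$frac_off_label > 0 && any(!lengths(off_pool))) {
    stop("no non-approved indication available for: ",
         paste(drugs[!lengths(off_pool)], collapse = ", "))
  }
  empty_posts <- data.frame(post_id = character(), source = character(),
                            drug_keyword = character(), text = character(),
                            created_at = character(), stringsAsFactors = FALSE)
  empty_truth <- data.frame(post_id = character(), relevant = logical(),
                            off_label_truth = logical(), ambiguous = logical(),
                            planted_pairs = I(list()), stringsAsFactors = FALSE)
  if (config$n_posts == 0L) return(list(posts = empty_posts, truth = empty_truth))

  vocab <- lexicon_token_vocabulary(lexicon)
  stop_list <- default_stopwords()

  with_seed(config$seed, {
    n <- config$n_posts
    posts <- vector("list", n)
    truths <- vector("list", n)
    for (i in seq_len(n)) {
      drug <- sample(drugs, 1L)
      relevant <- stats::runif(1) < config$frac_relevant
      pair <- NULL
      ambiguous <- FALSE
      if (relevant) {
        negated <- stats::runif(1) < config$negation_rate
        cross <- !negated && stats::runif(1) < config$cross_sentence_rate
        off <- stats::runif(1) < config$frac_off_label
        concept <- if (off) sample(off_pool[[drug]], 1L)
                   else sample(on_pool[[drug]], 1L)
        tmpl <- if (negated) sample(.relevant_templates_negated, 1L)
                else if (cross) sample(.relevant_templates_cross, 1L)
                else sample(.relevant_templates_plain, 1L)
        text <- gsub("{indication}", surfaces[[concept]],
                     gsub("{drug}", drug, tmpl, fixed = TRUE), fixed = TRUE)
        ambiguous <- stats::runif(1) < config$ambiguous_rate
        if (ambiguous) text <- paste0(text, .ambiguous_suffix)
        pair <- data.frame(drug = drug, indication = concept,
                           negated = negated, cross_sentence = cross,
                           stringsAsFactors = FALSE)
      } else {
        tmpl <- sample(.irrelevant_templates, 1L)
        text <- gsub("{drug}", drug, tmpl, fixed = TRUE)
      }
      if (stats::runif(1) < config$misspell_rate) {
        toks <- tokenize(text)
        eligible <- toks[nchar(toks) >= 4L & !(toks %in% stop_list) &
                           toks %in% vocab & grepl("^[a-z]+$", toks)]
        if (length(eligible)) {
          target <- sample(eligible, 1L)
          bad <- corrupt_token(target)
          # replace one whole-word occurrence, case-insensitively
          text <- sub(paste0("\\b", target, "\\b"), bad, text,
                      ignore.case = TRUE)
        }
      }
      posts[[i]] <- data.frame(
        post_id = sprintf("post%05d", i),
        source = sample(.ohc_sources, 1L),
        drug_keyword = drug, text = text, created_at = NA_character_,
        stringsAsFactors = FALSE)
      truths[[i]] <- data.frame(
        post_id = sprintf("post%05d", i), relevant = relevant,
        off_label_truth = relevant && !is.null(pair) && !pair$negated &&
          !(pair$indication %in% label_map$approved[[drug]]),
        ambiguous = ambiguous, stringsAsFactors = FALSE)
      truths[[i]]$planted_pairs <- I(list(pair))
    }
    list(posts = do.call(rbind, posts), truth = do.call(rbind, truths))
  })
}
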