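# Pipeline orchestration: relevance filter -> spell correction -> entity
# recognition -> non-medical filter -> dependency pairing with negation ->
# off-label flagging, with a per-stage count manifest (the post "funnel").

#' Default pipeline configuration
#'
#' @param posts,lexicon,label_map,model,output Optional paths; NULL means
#'   bundled defaults (lexicon, label map) or in-memory operation.
#' @param pairing [pairing_config()].
#' @param train [train_config()].
#' @param vectorizer [vectorizer_spec()].
#' @param generator Optional [generator_config()] (used by the generate
#'   subcommand).
#' @param similarity_threshold Embedding-filter threshold (0 = sign test).
#' @param seed Root seed governing every stochastic stage.
#' @param log_level `"info"` or `"quiet"`.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(posts = NULL, lexicon = NULL, label_map = NULL,
                            model = NULL, output = NULL,
                            pairing = pairing_config(),
                            train = train_config(),
                            vectorizer = vectorizer_spec("count_plus_tfidf"),
                            generator = NULL, similarity_threshold = 0,
                            seed = 1L, log_level = "info") {
  structure(list(paths = list(posts = posts, lexicon = lexicon,
                              label_map = label_map, model = model,
                              output = output),
                 pairing = pairing, train = train, vectorizer = vectorizer,
                 generator = generator,
                 similarity_threshold = similarity_threshold,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

pipeline_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) {
    message(sprintf("[offlabelr] %s", paste0(...)))
  }
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are an error (strict mode); omitted fields take the package
#' defaults (9-jump threshold, k = 10 folds, 0.2 test fraction, and so on).
#'
#' @param path YAML file.
#' @return \code{pipeline_config}.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("posts", "lexicon", "label_map", "model", "output", "pairing",
             "train", "vectorizer", "generator", "similarity_threshold",
             "seed", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  args <- raw[intersect(names(raw),
                        c("posts", "lexicon", "label_map", "model", "output",
                          "similarity_threshold", "seed", "log_level"))]
  if (!is.null(raw$pairing)) args$pairing <- do.call(pairing_config, raw$pairing)
  if (!is.null(raw$train)) args$train <- do.call(train_config, raw$train)
  if (!is.null(raw$vectorizer)) {
    args$vectorizer <- do.call(vectorizer_spec, raw$vectorizer)
  }
  if (!is.null(raw$generator)) {
    args$generator <- do.call(generator_config, raw$generator)
  }
  do.call(pipeline_config, args)
}

#' Dump a pipeline configuration to YAML
#'
#' Round-trips through [load_config()].
#'
#' @param config \code{pipeline_config}.
#' @param path Destination YAML file.
#' @export
dump_config <- function(config, path) {
  out <- config$paths
  out <- out[!vapply(out, is.null, logical(1))]
  out$pairing <- unclass(config$pairing)
  out$train <- unclass(config$train)
  out$vectorizer <- unclass(config$vectorizer)
  if (!is.null(config$generator)) out$generator <- unclass(config$generator)
  out$similarity_threshold <- config$similarity_threshold
  out$seed <- config$seed
  out$log_level <- config$log_level
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full off-label detection pipeline
#'
#' Stage order is fixed: relevance filter, spelling correction, entity
#' recognition, embedding-based non-medical filter, dependency pairing with
#' negation detection, off-label flagging against the label map. The run
#' manifest records input/output counts per stage (a non-increasing funnel).
#' Deterministic under a fixed seed.
#'
#' @param posts Post data.frame (see [read_posts()]).
#' @param config \code{pipeline_config}.
#' @param model Optional pre-trained \code{relevance_model}; if NULL,
#'   \code{labels} must supply training labels.
#' @param labels Optional logical relevance labels used to train a model
#'   in-run (synthetic-corpus evaluation mode).
#' @param lexicon,label_map Optional pre-loaded resources (bundled defaults
#'   otherwise).
#' @return List with \code{records} (off-label record data.frame),
#'   \code{pairs}, \code{mentions}, \code{relevant} (logical per post) and
#'   \code{manifest} (stage counts).
#' @export
run_pipeline <- function(posts, config = pipeline_config(), model = NULL,
                         labels = NULL, lexicon = NULL, label_map = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(lexicon)) {
    lexicon <- read_lexicon(config$paths$lexicon)
  }
  if (is.null(label_map)) label_map <- load_label_map(config$paths$label_map)
  manifest <- list(n_input = nrow(posts))
  if (!nrow(posts)) {
    manifest[c("n_relevant", "n_spell_corrected", "n_with_mentions",
               "n_after_filter", "n_with_pairs", "n_records",
               "n_off_label")] <- 0L
    return(list(records = empty_off_label_records(),
                pairs = NULL, mentions = NULL, relevant = logical(),
                manifest = manifest))
  }

  # stage 1: relevance classification
  if (is.null(model)) {
    if (is.null(labels)) {
      stop("run_pipeline needs a trained model or training labels")
    }
    model <- train_relevance_classifier(
      posts$text, labels, config$vectorizer,
      train_config(test_fraction = config$train$test_fraction,
                   k_folds = config$train$k_folds,
                   classifier = config$train$classifier,
                   seed = child_seed(config$seed, "relevance")))
  }
  relevant <- classify_relevance(model, posts$text)
  kept <- posts[relevant, , drop = FALSE]
  manifest$n_relevant <- nrow(kept)
  pipeline_log(config, "relevance: ", nrow(posts), " -> ", nrow(kept))
  if (!nrow(kept)) {
    manifest[c("n_spell_corrected", "n_with_mentions", "n_after_filter",
               "n_with_pairs", "n_records", "n_off_label")] <- 0L
    return(list(records = empty_off_label_records(), pairs = NULL,
                mentions = list(), relevant = relevant, model = model,
                manifest = manifest))
  }

  # stage 2: spelling normalization
  spell_index <- structure(build_spell_index(lexicon), class = "spell_index")
  corrected <- vapply(kept$text, function(t)
    correct_text(t, spell_index)$text, character(1), USE.NAMES = FALSE)
  manifest$n_spell_corrected <- length(corrected)

  # stage 3: entity recognition
  mentions_by_post <- lapply(seq_len(nrow(kept)), function(i)
    recognize_entities(corrected[[i]], lexicon, kept$post_id[[i]]))
  has_mentions <- vapply(mentions_by_post, nrow, integer(1)) > 0L
  manifest$n_with_mentions <- sum(has_mentions)
  pipeline_log(config, "entities: ", sum(has_mentions),
               " posts with mentions")

  # stage 4: non-medical filter (skipped per post when the drug has no
  # embedding vector)
  emb <- train_embeddings(tokenize_corpus(corrected), d = 100L, window = 5L,
                          min_count = 2L,
                          seed = child_seed(config$seed, "embeddings"))
  mentions_by_post <- lapply(seq_len(nrow(kept)), function(i) {
    m <- mentions_by_post[[i]]
    kw <- kept$drug_keyword[[i]]
    if (nrow(m) && kw %in% rownames(emb$vectors)) {
      filter_nonmedical(kw, m, emb, config$similarity_threshold)
    } else m
  })
  manifest$n_after_filter <-
    sum(vapply(mentions_by_post, nrow, integer(1)) > 0L)

  # stage 5: dependency pairing + negation
  pairs <- lapply(seq_len(nrow(kept)), function(i) {
    extract_pairs(kept[i, , drop = FALSE], mentions_by_post[[i]],
                  parse_post(corrected[[i]]), config$pairing)
  })
  pairs <- do.call(rbind, pairs[vapply(pairs, nrow, integer(1)) > 0L])
  if (is.null(pairs)) {
    pairs <- data.frame(post_id = character(), drug = character(),
                        drug_surface = character(), indication = character(),
                        indication_surface = character(),
                        jump_distance = integer(), same_sentence = logical(),
                        substitution_used = logical(), negated = logical(),
                        stringsAsFactors = FALSE)
  }
  manifest$n_with_pairs <- length(unique(pairs$post_id))
  pipeline_log(config, "pairing: ", nrow(pairs), " pairs in ",
               manifest$n_with_pairs, " posts")

  # stage 6: off-label flagging
  records <- flag_pairs(pairs, label_map)
  manifest$n_records <- nrow(records)
  manifest$n_off_label <- length(unique(records$post_id[records$off_label]))
  pipeline_log(config, "off-label: ", manifest$n_off_label, " flagged posts")

  if (!is.null(config$paths$output)) {
    fmt <- if (grepl("\\.jsonl$", config$paths$output)) "jsonl" else "csv"
    write_records(records, config$paths$output, fmt)
  }
  list(records = records, pairs = pairs, mentions = mentions_by_post,
       relevant = relevant, model = model, manifest = manifest)
}
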