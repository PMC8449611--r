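# Relevance classification: separates firsthand patient-experience posts
# from general chatter. Vectorization follows the study design: bag-of-words
# counts and TF-IDF capped at 900 features each, their concatenation capped
# at 450 + 450, or a 300-dimension document embedding; classifiers span a
# classic grid with gradient-boosted trees on the count+TF-IDF ensemble as
# the selected model.

#' Vectorizer specification
#'
#' @param scheme One of `"count"`, `"tfidf"`, `"count_plus_tfidf"`,
#'   `"doc_embedding"`.
#' @param max_features Feature cap: 900 for the single schemes, 450 + 450 for
#'   the concatenated ensemble, 300 for the document embedding.
#' @param remove_stopwords Drop bundled English stopwords before counting.
#' @return List of class \code{vectorizer_spec}.
#' @export
vectorizer_spec <- function(scheme = c("count", "tfidf", "count_plus_tfidf",
                                       "doc_embedding"),
                            max_features = NULL, remove_stopwords = FALSE) {
  scheme <- match.arg(scheme)
  if (is.null(max_features)) {
    max_features <- if (scheme == "doc_embedding") 300L else 900L
  }
  if (max_features < 1L) stop("max_features must be positive")
  structure(list(scheme = scheme, max_features = as.integer(max_features),
                 remove_stopwords = isTRUE(remove_stopwords)),
            class = "vectorizer_spec")
}

tokenize_corpus <- function(texts, remove_stopwords = FALSE) {
  toks <- lapply(texts, tokenize)
  if (remove_stopwords) {
    sw <- default_stopwords()
    toks <- lapply(toks, function(t) t[!(t %in% sw)])
  }
  toks
}

# vocabulary = the max_features highest-total-frequency terms, ties broken
# lexicographically (deterministic)
select_vocabulary <- function(token_lists, max_features) {
  counts <- table(unlist(token_lists, use.names = FALSE))
  if (!length(counts)) stop("empty vocabulary: no tokens in corpus")
  ord <- order(-as.integer(counts), names(counts))
  names(counts)[ord][seq_len(min(max_features, length(counts)))]
}

count_matrix <- function(token_lists, vocabulary) {
  m <- matrix(0, length(token_lists), length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(token_lists)) {
    tab <- table(token_lists[[i]])
    hit <- intersect(names(tab), vocabulary)
    if (length(hit)) m[i, hit] <- as.integer(tab[hit])
  }
  m
}

# smoothed idf: log((1 + n) / (1 + df)) + 1
idf_weights <- function(counts) {
  n <- nrow(counts)
  df <- colSums(counts > 0)
  log((1 + n) / (1 + df)) + 1
}

#' Fit a vectorizer and transform a corpus
#'
#' Fits the vocabulary (and scheme-specific state) on \code{texts} and
#' returns the document-feature matrix together with the fitted vectorizer.
#' Refitting on the same corpus is identical. For the concatenated
#' \code{count_plus_tfidf} scheme each half is capped at
#' \code{max_features / 2}.
#'
#' @param texts Non-empty character vector.
#' @param spec [vectorizer_spec()].
#' @param embeddings Optional [train_embeddings()] table for the
#'   \code{doc_embedding} scheme; fitted on the corpus when omitted.
#' @return List with \code{matrix} (documents x features) and
#'   \code{vectorizer} (reusable via [vectorize_transform()]).
#' @export
vectorize <- function(texts, spec = vectorizer_spec(), embeddings = NULL) {
  if (!length(texts)) stop("cannot fit a vectorizer on an empty corpus")
  toks <- tokenize_corpus(texts, spec$remove_stopwords)
  state <- list(spec = spec)
  if (spec$scheme == "count") {
    vocab <- select_vocabulary(toks, spec$max_features)
    state$vocabulary <- vocab
    m <- count_matrix(toks, vocab)
  } else if (spec$scheme == "tfidf") {
    vocab <- select_vocabulary(toks, spec$max_features)
    state$vocabulary <- vocab
    counts <- count_matrix(toks, vocab)
    state$idf <- idf_weights(counts)
    m <- sweep(counts, 2, state$idf, `*`)
  } else if (spec$scheme == "count_plus_tfidf") {
    half <- spec$max_features %/% 2L
    vocab <- select_vocabulary(toks, half)
    state$vocabulary <- vocab
    counts <- count_matrix(toks, vocab)
    state$idf <- idf_weights(counts)
    colnames(counts) <- paste0("count_", vocab)
    tfidf <- sweep(count_matrix(toks, vocab), 2, state$idf, `*`)
    colnames(tfidf) <- paste0("tfidf_", vocab)
    m <- cbind(counts, tfidf)
  } else { # doc_embedding
    if (is.null(embeddings)) {
      embeddings <- train_embeddings(toks, d = spec$max_features,
                                     min_count = 1L)
    }
    state$embeddings <- embeddings
    m <- doc_embedding_matrix(toks, embeddings, spec$max_features)
  }
  vec <- structure(state, class = "ohc_vectorizer")
  list(matrix = m, vectorizer = vec)
}

doc_embedding_matrix <- function(token_lists, embeddings, d) {
  vecs <- embeddings$vectors
  d_use <- min(d, ncol(vecs))
  m <- matrix(0, length(token_lists), d_use)
  for (i in seq_along(token_lists)) {
    hit <- intersect(token_lists[[i]], rownames(vecs))
    if (length(hit)) {
      m[i, ] <- colMeans(vecs[hit, seq_len(d_use), drop = FALSE])
    }
  }
  colnames(m) <- paste0("dim", seq_len(d_use))
  m
}

#' Transform new texts with a fitted vectorizer
#'
#' @param vectorizer Fitted vectorizer from [vectorize()].
#' @param texts Character vector.
#' @return Document-feature matrix with the fitted feature space.
#' @export
vectorize_transform <- function(vectorizer, texts) {
  stopifnot(inherits(vectorizer, "ohc_vectorizer"))
  spec <- vectorizer$spec
  toks <- tokenize_corpus(texts, spec$remove_stopwords)
  if (spec$scheme == "count") {
    count_matrix(toks, vectorizer$vocabulary)
  } else if (spec$scheme == "tfidf") {
    sweep(count_matrix(toks, vectorizer$vocabulary), 2, vectorizer$idf, `*`)
  } else if (spec$scheme == "count_plus_tfidf") {
    counts <- count_matrix(toks, vectorizer$vocabulary)
    tfidf <- sweep(counts, 2, vectorizer$idf, `*`)
    colnames(counts) <- paste0("count_", vectorizer$vocabulary)
    colnames(tfidf) <- paste0("tfidf_", vectorizer$vocabulary)
    cbind(counts, tfidf)
  } else {
    doc_embedding_matrix(toks, vectorizer$embeddings, spec$max_features)
  }
}

#' Training configuration for the relevance classifier
#'
#' @param test_fraction Held-out fraction (default 0.2, the 80/20 split).
#' @param k_folds Cross-validation folds (default 10).
#' @param classifier One of `"svm"`, `"naive_bayes"`, `"sgd_linear"`,
#'   `"random_forest"`, `"gradient_boosted_trees"` (the selected model).
#' @param seed Integer seed for the split and any stochastic fit.
#' @return List of class \code{train_config}.
#' @export
train_config <- function(test_fraction = 0.2, k_folds = 10L,
                         classifier = c("gradient_boosted_trees", "svm",
                                        "naive_bayes", "sgd_linear",
                                        "random_forest"),
                         seed = 1L) {
  classifier <- match.arg(classifier)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  if (k_folds < 2L) stop("k_folds must be >= 2")
  structure(list(test_fraction = test_fraction, k_folds = as.integer(k_folds),
                 classifier = classifier, seed = as.integer(seed)),
            class = "train_config")
}

# Bernoulli feature view for naive Bayes: term presence/absence as factors
nb_features <- function(x) {
  as.data.frame(lapply(as.data.frame(x > 0), factor, levels = c(FALSE, TRUE)))
}

fit_classifier <- function(x, y, classifier, seed) {
  y <- factor(y, levels = c(FALSE, TRUE))
  switch(classifier,
    svm = e1071::svm(x, y, kernel = "linear", scale = FALSE),
    naive_bayes = e1071::naiveBayes(nb_features(x), y, laplace = 1),
    sgd_linear = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                                lambda = 0.001),
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = 200L, seed = seed,
      num.threads = 1L),
    gradient_boosted_trees = xgboost::xgboost(
      x = x, y = y, nrounds = 60L, max_depth = 4L, learning_rate = 0.3,
      nthreads = 1L, seed = seed, verbosity = 0L))
}

predict_classifier <- function(fit, classifier, x) {
  if (classifier == "svm") {
    as.logical(predict(fit, x) == "TRUE")
  } else if (classifier == "naive_bayes") {
    as.logical(predict(fit, nb_features(x)) == "TRUE")
  } else if (classifier == "sgd_linear") {
    as.numeric(predict(fit, x, type = "response")) > 0.5
  } else if (classifier == "random_forest") {
    as.logical(predict(fit, data = as.data.frame(x),
                       num.threads = 1L)$predictions == "TRUE")
  } else {
    as.numeric(predict(fit, x)) > 0.5
  }
}

#' Train the relevance classifier
#'
#' Fits the vectorizer on the training split (a seeded, stratified 80/20
#' split by default), trains the configured classifier and reports held-out
#' metrics computed by [metrics_from_cm()]. Deterministic for a fixed seed.
#'
#' @param texts Post texts.
#' @param labels Logical relevance labels (both classes must be present).
#' @param spec [vectorizer_spec()]; the study's selected configuration is
#'   \code{count_plus_tfidf} with 900 total features.
#' @param cfg [train_config()].
#' @return Object of class \code{relevance_model} with a held-out
#'   \code{metrics} report.
#' @export
train_relevance_classifier <- function(texts, labels,
                                       spec = vectorizer_spec("count_plus_tfidf"),
                                       cfg = train_config()) {
  if (!length(texts)) stop("empty training corpus")
  if (length(texts) != length(labels)) stop("texts and labels differ in length")
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class")
  }
  n <- length(texts)
  test_idx <- with_seed(cfg$seed, {
    idx <- unlist(lapply(split(seq_len(n), labels), function(grp) {
      k <- max(1L, round(length(grp) * cfg$test_fraction))
      sample(grp, k)
    }), use.names = FALSE)
    sort(idx)
  })
  train_idx <- setdiff(seq_len(n), test_idx)
  fitted <- vectorize(texts[train_idx], spec)
  fit <- with_seed(cfg$seed,
                   fit_classifier(fitted$matrix, labels[train_idx],
                                  cfg$classifier, cfg$seed))
  model <- structure(list(vectorizer = fitted$vectorizer, fit = fit,
                          classifier = cfg$classifier, spec = spec, cfg = cfg,
                          version = "1"),
                     class = "relevance_model")
  pred <- classify_relevance(model, texts[test_idx])
  cm <- confusion_matrix(pred, labels[test_idx])
  model$metrics <- metrics_from_cm(cm)
  model$holdout_cm <- cm
  model
}

#' @export
print.relevance_model <- function(x, ...) {
  cat("<relevance_model> classifier=", x$classifier, ", scheme=",
      x$spec$scheme, " (", x$spec$max_features, " features)\n", sep = "")
  if (!is.null(x$metrics)) {
    cat("held-out: "); print(x$metrics)
  }
  invisible(x)
}

#' Classify posts as relevant or not
#'
#' Pure function of the fitted model and the texts.
#'
#' @param model \code{relevance_model}.
#' @param texts Character vector of post texts.
#' @return Logical vector, one flag per post.
#' @export
classify_relevance <- function(model, texts) {
  if (!inherits(model, "relevance_model") || is.null(model$fit)) {
    stop("model is not a fitted relevance_model")
  }
  if (!length(texts)) return(logical())
  x <- vectorize_transform(model$vectorizer, texts)
  predict_classifier(model$fit, model$classifier, x)
}

#' @export
predict.relevance_model <- function(object, newdata, ...) {
  classify_relevance(object, newdata)
}

#' k-fold cross-validation of the relevance classifier
#'
#' Seeded fold assignment partitioning the data (every sample in exactly one
#' validation fold); per-fold metrics plus mean/sd summaries.
#'
#' @inheritParams train_relevance_classifier
#' @return List with \code{folds} (list of \code{metrics_report}),
#'   \code{mean_accuracy}, \code{sd_accuracy}, \code{mean_f1}, \code{sd_f1},
#'   \code{assignments} (fold id per sample).
#' @export
kfold_cv <- function(texts, labels, spec = vectorizer_spec("count_plus_tfidf"),
                     cfg = train_config()) {
  n <- length(texts)
  labels <- as.logical(labels)
  if (cfg$k_folds > n) stop("k_folds exceeds the number of samples")
  assignments <- with_seed(cfg$seed,
                           sample(rep(seq_len(cfg$k_folds), length.out = n)))
  reports <- vector("list", cfg$k_folds)
  for (k in seq_len(cfg$k_folds)) {
    val <- which(assignments == k)
    tr <- which(assignments != k)
    fitted <- vectorize(texts[tr], spec)
    fit <- with_seed(cfg$seed + k,
                     fit_classifier(fitted$matrix, labels[tr],
                                    cfg$classifier, cfg$seed + k))
    x_val <- vectorize_transform(fitted$vectorizer, texts[val])
    pred <- predict_classifier(fit, cfg$classifier, x_val)
    reports[[k]] <- metrics_from_cm(confusion_matrix(pred, labels[val]))
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  f1 <- vapply(reports, `[[`, numeric(1), "f1")
  list(folds = reports, mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
       mean_f1 = mean(f1, na.rm = TRUE), sd_f1 = stats::sd(f1, na.rm = TRUE),
       assignments = assignments)
}

#' Save / load a fitted relevance model
#'
#' Single-file serialized bundle (vocabulary, weights, provenance), versioned.
#'
#' @param model \code{relevance_model}.
#' @param path Destination file.
#' @export
save_relevance_model <- function(model, path) {
  stopifnot(inherits(model, "relevance_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_relevance_model
#' @export
load_relevance_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "relevance_model")) {
    stop("file does not contain a relevance_model: ", path)
  }
  model
}
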