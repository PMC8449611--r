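#' Read posts from a line-delimited JSON file
#'
#' One post per line, UTF-8, fields \code{post_id}, \code{source},
#' \code{drug_keyword}, \code{text} (all required) and optional
#' \code{created_at} (ISO-8601 string).
#'
#' @param path Path to a JSONL file.
#' @return data.frame with one row per post, in file order.
#' @export
read_posts <- function(path) {
  if (!file.exists(path)) stop("posts file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(post_id = character(), source = character(),
                      drug_keyword = character(), text = character(),
                      created_at = character(), stringsAsFactors = FALSE))
  }
  required <- c("post_id", "source", "drug_keyword", "text")
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("line ", i, ": invalid JSON (",
                                             conditionMessage(e), ")"))
    missing <- setdiff(required, names(rec))
    missing <- union(missing,
                     required[vapply(required, function(f)
                       !is.null(rec[[f]]) && !nzchar(as.character(rec[[f]])),
                       logical(1))])
    if (length(missing)) {
      stop("line ", i, ": missing required field(s): ",
           paste(sort(missing), collapse = ", "))
    }
    rows[[i]] <- data.frame(
      post_id = as.character(rec$post_id),
      source = as.character(rec$source),
      drug_keyword = tolower(as.character(rec$drug_keyword)),
      text = as.character(rec$text),
      created_at = if (is.null(rec$created_at)) NA_character_
                   else as.character(rec$created_at),
      stringsAsFactors = FALSE)
  }
  posts <- do.call(rbind, rows)
  dup <- duplicated(posts$post_id)
  if (any(dup)) {
    stop("duplicate post_id: ", paste(unique(posts$post_id[dup]), collapse = ", "))
  }
  posts
}

#' Write posts to a line-delimited JSON file
#'
#' @param posts data.frame as returned by [read_posts()].
#' @param path Output path.
#' @export
write_posts <- function(posts, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(posts))) {
    rec <- as.list(posts[i, , drop = FALSE])
    rec <- lapply(rec, function(v) v[[1]])
    if (is.na(rec$created_at)) rec$created_at <- NULL
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

off_label_record_columns <- c(
  "post_id", "drug", "indication", "off_label", "confidence",
  "jump_distance", "same_sentence", "substitution_used", "negated")

empty_off_label_records <- function() {
  data.frame(post_id = character(), drug = character(),
             indication = character(), off_label = logical(),
             confidence = character(), jump_distance = integer(),
             same_sentence = logical(), substitution_used = logical(),
             negated = logical(), stringsAsFactors = FALSE)
}

#' Write off-label records
#'
#' Deterministic column order; CSV uses RFC 4180 quoting. A round-trip through
#' [read_records()] returns identical records.
#'
#' @param records data.frame of off-label records (see [flag_off_label()]).
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @export
write_records <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  records <- records[, off_label_record_columns, drop = FALSE]
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(records))) {
      rec <- lapply(as.list(records[i, , drop = FALSE]), function(v) v[[1]])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read off-label records written by [write_records()]
#'
#' @inheritParams write_records
#' @return data.frame with the canonical record columns.
#' @export
read_records <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(
                             post_id = "character", drug = "character",
                             indication = "character", off_label = "logical",
                             confidence = "character",
                             jump_distance = "integer",
                             same_sentence = "logical",
                             substitution_used = "logical",
                             negated = "logical"))
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(empty_off_label_records())
    out <- do.call(rbind, lapply(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      data.frame(post_id = rec$post_id, drug = rec$drug,
                 indication = rec$indication,
                 off_label = as.logical(rec$off_label),
                 confidence = rec$confidence,
                 jump_distance = as.integer(rec$jump_distance),
                 same_sentence = as.logical(rec$same_sentence),
                 substitution_used = as.logical(rec$substitution_used),
                 negated = as.logical(rec$negated),
                 stringsAsFactors = FALSE)
    }))
  }
  out[, off_label_record_columns, drop = FALSE]
}

#' Write and read ground-truth sidecar files
#'
#' Ground truth for a synthetic corpus is stored as JSONL keyed by
#' \code{post_id}; planted drug–indication pairs travel as nested objects.
#'
#' @param truth data.frame as returned by [generate_synthetic_corpus()].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(truth))) {
    rec <- list(post_id = truth$post_id[i], relevant = truth$relevant[i],
                off_label_truth = truth$off_label_truth[i],
                ambiguous = truth$ambiguous[i],
                planted_pairs = truth$planted_pairs[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    post_id = vapply(recs, function(r) r$post_id, character(1)),
    relevant = vapply(recs, function(r) r$relevant, logical(1)),
    off_label_truth = vapply(recs, function(r) r$off_label_truth, logical(1)),
    ambiguous = vapply(recs, function(r) isTRUE(r$ambiguous), logical(1)),
    planted_pairs = I(lapply(recs, function(r) {
      p <- r$planted_pairs
      if (is.null(p) || (is.data.frame(p) && !nrow(p))) NULL else p
    })),
    stringsAsFactors = FALSE)
}
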