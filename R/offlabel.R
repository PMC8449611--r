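# Comparison of retained drug–indication pairs against the FDA-approved
# indication map (bundled, openFDA-compatible JSON) and emission of
# per-pair off-label records with confidence buckets.

#' Load a drug -> approved-indication map
#'
#' JSON layout: \code{{drug: {approved: [concepts], synonyms: {surface:
#' concept}}}}; a reserved top-level \code{"_shared_synonyms"} object holds
#' surface variants shared across drugs. The bundled default covers the 12
#' study drugs (6 positive-cohort, 6 negative-cohort).
#'
#' @param path JSON file; defaults to the bundled map.
#' @return Object of class \code{label_map}: list with \code{approved} (named
#'   list drug -> character vector of concepts) and \code{synonyms} (named
#'   character vector surface -> concept, including the identity for every
#'   approved concept).
#' @export
load_label_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fda_label_map.json", package = "offlabelr")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  shared <- raw[["_shared_synonyms"]]
  raw[["_shared_synonyms"]] <- NULL
  approved <- list(); synonyms <- character()
  for (drug in names(raw)) {
    entry <- raw[[drug]]
    app <- tolower(unlist(entry$approved, use.names = FALSE))
    if (!length(app)) warning("drug with empty approved set: ", drug)
    approved[[tolower(drug)]] <- app
    syn <- entry$synonyms
    if (length(syn)) {
      synonyms[tolower(names(syn))] <- tolower(unlist(syn, use.names = FALSE))
    }
    synonyms[app] <- app
  }
  if (length(shared)) {
    synonyms[tolower(names(shared))] <-
      tolower(unlist(shared, use.names = FALSE))
  }
  structure(list(approved = approved, synonyms = synonyms),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", length(x$approved), " drugs, ",
      length(unique(unlist(x$approved))), " approved concepts, ",
      length(x$synonyms), " synonym entries\n", sep = "")
  invisible(x)
}

#' Normalize an indication surface to a concept
#'
#' Lowercases, trims and canonicalizes the surface, then applies the synonym
#' table. Unknown surfaces map to themselves (as novel concepts).
#'
#' @param surface Indication surface string.
#' @param label_map [load_label_map()] result.
#' @return Concept id string.
#' @export
normalize_indication <- function(surface, label_map) {
  s <- tolower(trimws(surface))
  if (s %in% names(label_map$synonyms)) return(unname(label_map$synonyms[s]))
  canon <- gsub("^_+|_+$", "", gsub("[^a-z0-9]+", "_", s))
  if (canon %in% names(label_map$synonyms)) {
    return(unname(label_map$synonyms[canon]))
  }
  canon
}

#' Assign a confidence bucket to a retained pair
#'
#' \code{high}: same-sentence pair at jump distance <= \code{high_max};
#' \code{medium}: same-sentence pair farther than that (but retained);
#' \code{low}: cross-sentence pair formed via substitution.
#'
#' @param pair One-row pair data.frame from [extract_pairs()].
#' @param high_max Inclusive distance bound for the high bucket (default 4).
#' @return `"high"`, `"medium"` or `"low"`.
#' @export
assign_confidence <- function(pair, high_max = 4L) {
  if (isTRUE(pair$substitution_used) || !isTRUE(pair$same_sentence)) {
    return("low")
  }
  if (pair$jump_distance <= high_max) "high" else "medium"
}

#' Flag a retained pair as off-label or not
#'
#' A pair is off-label iff it is not negated and its normalized indication
#' concept is absent from the drug's approved set. Negated pairs are always
#' flagged not off-label.
#'
#' @param pair One-row pair data.frame from [extract_pairs()].
#' @param label_map [load_label_map()] result.
#' @return One-row off-label record data.frame (columns \code{post_id},
#'   \code{drug}, \code{indication}, \code{off_label}, \code{confidence},
#'   \code{jump_distance}, \code{same_sentence}, \code{substitution_used},
#'   \code{negated}).
#' @export
flag_off_label <- function(pair, label_map) {
  drug <- tolower(pair$drug)
  if (!(drug %in% names(label_map$approved))) {
    stop("drug not in label map, cannot adjudicate: ", drug)
  }
  concept <- normalize_indication(pair$indication, label_map)
  off <- !isTRUE(pair$negated) && !(concept %in% label_map$approved[[drug]])
  data.frame(post_id = pair$post_id, drug = drug, indication = concept,
             off_label = off, confidence = assign_confidence(pair),
             jump_distance = as.integer(pair$jump_distance),
             same_sentence = pair$same_sentence,
             substitution_used = pair$substitution_used,
             negated = pair$negated, stringsAsFactors = FALSE)
}

#' Flag every pair in a pair table
#'
#' @param pairs data.frame from [extract_pairs()].
#' @param label_map [load_label_map()] result.
#' @return data.frame of off-label records (possibly zero rows).
#' @export
flag_pairs <- function(pairs, label_map) {
  if (!nrow(pairs)) return(empty_off_label_records())
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    flag_off_label(pairs[i, , drop = FALSE], label_map)))
}

#' Fetch a drug label from the openFDA API (optional, network)
#'
#' Downloads the drug-label record, caches the raw JSON to disk and extracts
#' the \code{indications_and_usage} section. Never used by the bundled tests;
#' the packaged label map is the offline source of truth.
#'
#' @param drug_name Drug name to query.
#' @param cache_dir Directory for cached raw responses.
#' @param offline If TRUE, refuse with an informative error.
#' @return List with \code{raw_path} and \code{indications} (character).
#' @export
fetch_label <- function(drug_name, cache_dir = tempdir(), offline = FALSE) {
  if (isTRUE(offline)) {
    stop("offline mode: fetch_label refuses to reach the openFDA API; ",
         "use the bundled label map instead")
  }
  url <- paste0(
    "https://api.fda.gov/drug/label.json?search=openfda.generic_name:%22",
    utils::URLencode(tolower(drug_name), reserved = TRUE), "%22&limit=1")
  resp <- tryCatch(jsonlite::fromJSON(url), error = function(e)
    stop("openFDA request failed (check network and retry): ",
         conditionMessage(e)))
  if (is.null(resp$results) || !length(resp$results)) {
    stop("drug not found in openFDA: ", drug_name)
  }
  ind <- resp$results$indications_and_usage
  if (is.null(ind)) stop("label for ", drug_name,
                         " has no indications_and_usage section")
  raw_path <- file.path(cache_dir, paste0("openfda_",
                                          gsub("[^a-z0-9]+", "_",
                                               tolower(drug_name)), ".json"))
  jsonlite::write_json(resp, raw_path, auto_unbox = TRUE)
  list(raw_path = raw_path, indications = unlist(ind, use.names = FALSE))
}
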