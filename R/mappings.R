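#' Ontology-term mapping repository
#'
#' Different ontologies often assign different URIs to the same real-world
#' concept (e.g. `ncit:C12801` and `obo:UBERON_0000479` both denote 'tissue').
#' A mapping repository stores pairwise equivalence assertions between term
#' URIs and closes them reflexively, symmetrically and transitively: the
#' equivalence classes are the connected components of the mapping graph.
#' URI-level matching throughout the package is done on class representatives
#' (the lexicographically smallest URI of the class), so replacing any URI by
#' an equivalent one never changes a result.
#'
#' @param pairs A data frame with character columns `a` and `b` (one mapping
#'   assertion per row), or `NULL`/zero rows for the empty repository in which
#'   every term is equivalent only to itself.
#' @return An object of class `term_mappings`.
#' @examples
#' m <- term_mappings(data.frame(a = "ncit:C12801", b = "obo:UBERON_0000479"))
#' equivalent_terms(m, "ncit:C12801")
#' @export
term_mappings <- function(pairs = NULL) {
  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0) {
    return(structure(
      list(representative = character(),
           pairs = tibble(a = character(), b = character())),
      class = "term_mappings"
    ))
  }
  pairs <- as_tibble(pairs)[, c("a", "b")]
  pairs <- mutate(pairs, a = trimws(.data$a), b = trimws(.data$b))
  if (any(!nzchar(pairs$a)) || any(!nzchar(pairs$b))) {
    abort("mapping assertions require non-empty URIs")
  }
  uris <- sort(unique(c(pairs$a, pairs$b)))
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                     vertices = uris)
  comp <- igraph::components(g)$membership
  rep_by_class <- tapply(names(comp), comp, min)
  structure(
    list(representative = setNames(unname(rep_by_class[as.character(comp)]),
                                   names(comp)),
         pairs = pairs),
    class = "term_mappings"
  )
}

#' @export
print.term_mappings <- function(x, ...) {
  k <- length(unique(x$representative))
  cat("<term_mappings> ", length(x$representative), " URIs in ", k,
      " equivalence class", if (k != 1) "es", "\n", sep = "")
  invisible(x)
}

#' @param mappings A `term_mappings` object (or `NULL` for no mappings).
#' @param uri A single term URI.
#' @return `equivalent_terms()`: character vector of all URIs equivalent to
#'   `uri`, always including `uri` itself; an unknown URI is equivalent only
#'   to itself.
#' @rdname term_mappings
#' @export
equivalent_terms <- function(mappings, uri) {
  stopifnot(length(uri) == 1, is.character(uri))
  rep <- term_representative(mappings, uri)
  known <- names(mappings$representative)[mappings$representative == rep]
  sort(unique(c(uri, known)))
}

#' Canonical class representative of term URIs
#'
#' Vectorized: URIs absent from the mapping repository represent themselves.
#'
#' @inheritParams equivalent_terms
#' @param uris Character vector of URIs (`NA` passes through).
#' @return Character vector of representatives, same length as `uris`.
#' @export
term_representative <- function(mappings, uris) {
  if (is.null(mappings) || length(mappings$representative) == 0) return(uris)
  hit <- match(uris, names(mappings$representative))
  out <- uris
  found <- !is.na(hit)
  out[found] <- unname(mappings$representative[hit[found]])
  out
}

#' Do two field--value pairs match?
#'
#' In text mode two pairs match when both the field labels and the value
#' labels are equal (case-sensitively, after whitespace trimming). In ontology
#' mode matching is at the semantic level: the field URIs must fall in the
#' same equivalence class of the mapping repository, and so must the value
#' URIs.
#'
#' @param p,q One-row data frames (or lists) with `field_label`, `value_label`
#'   and, for ontology mode, `field_uri`, `value_uri`.
#' @inheritParams equivalent_terms
#' @param mode `"text"` or `"ontology"`.
#' @return Logical scalar.
#' @export
pairs_match <- function(p, q, mappings = NULL, mode = c("text", "ontology")) {
  mode <- match.arg(mode)
  p <- as_context(as.data.frame(p))
  q <- as_context(as.data.frame(q))
  stopifnot(nrow(p) == 1, nrow(q) == 1)
  pair_key(p, mappings, mode) == pair_key(q, mappings, mode)
}

# canonical encoding of field-value pairs; the unit of all set arithmetic
# (transactions, Jaccard context matching, candidate dedup)
pair_key <- function(df, mappings, mode) {
  paste0(field_key(df, mappings, mode), "\x1f",
         value_key(df, mappings, mode))
}

field_key <- function(df, mappings, mode) {
  if (mode == "text") {
    trimws(df$field_label)
  } else {
    uri <- df$field_uri
    if (any(is.na(uri))) abort("ontology mode requires field URIs on all pairs")
    term_representative(mappings, uri)
  }
}

value_key <- function(df, mappings, mode) {
  if (mode == "text") {
    trimws(df$value_label)
  } else {
    uri <- df$value_uri
    if (any(is.na(uri))) abort("ontology mode requires value URIs on all pairs")
    term_representative(mappings, uri)
  }
}

#' Annotation lexicon
#'
#' A dictionary annotator that links free-text labels to ontology-term URIs,
#' playing the role an annotation service plays in a production setting. Each
#' entry maps a text label to exactly one canonical term URI and carries the
#' term's preferred label. Lookup normalizes the query by whitespace-trimming
#' and case-folding (annotation, unlike text-mode matching, is meant to unify
#' variants like 'male'/'Male'/'M'); matching is exact after normalization, no
#' fuzzy matching.
#'
#' @param entries Data frame with columns `label`, `uri` and optionally
#'   `preferred_label` (defaults to the label of the first entry for each URI).
#' @return An `annotation_lexicon` object.
#' @examples
#' lex <- annotation_lexicon(data.frame(
#'   label = c("serum hepatitis", "hepatitis B"),
#'   uri = "obo:DOID_2043", preferred_label = "hepatitis B"
#' ))
#' @export
annotation_lexicon <- function(entries) {
  entries <- as_tibble(entries)
  if (!"preferred_label" %in% names(entries)) {
    entries$preferred_label <- NA_character_
  }
  entries <- entries %>%
    mutate(label = trimws(.data$label), uri = trimws(.data$uri),
           key = tolower(.data$label))
  # case variants of one label that agree on the URI collapse to one entry;
  # the same normalized label pointing at two URIs is ambiguous
  conflict <- entries %>%
    distinct(.data$key, .data$uri) %>%
    count(.data$key) %>%
    filter(n > 1)
  if (nrow(conflict) > 0) {
    abort(paste0("lexicon label resolves to more than one term: '",
                 conflict$key[1], "'"))
  }
  entries <- distinct(entries, .data$key, .keep_all = TRUE)
  # one preferred label per URI
  pref <- entries %>%
    group_by(.data$uri) %>%
    summarise(preferred_label = {
      p <- .data$preferred_label[!is.na(.data$preferred_label)]
      if (length(p) > 0) p[1] else .data$label[1]
    }, .groups = "drop")
  entries <- entries %>%
    select(-"preferred_label") %>%
    left_join(pref, by = "uri")
  structure(list(entries = entries), class = "annotation_lexicon")
}

#' @export
print.annotation_lexicon <- function(x, ...) {
  cat("<annotation_lexicon> ", nrow(x$entries), " labels -> ",
      length(unique(x$entries$uri)), " terms\n", sep = "")
  invisible(x)
}

#' Look up labels in a lexicon
#'
#' @param lexicon An [annotation_lexicon()].
#' @param labels Character vector of text labels.
#' @return Tibble with columns `label`, `uri`, `preferred_label`; `NA` URI for
#'   labels absent from the lexicon.
#' @export
lookup_terms <- function(lexicon, labels) {
  hit <- match(tolower(trimws(labels)), lexicon$entries$key)
  tibble(label = labels,
         uri = lexicon$entries$uri[hit],
         preferred_label = lexicon$entries$preferred_label[hit])
}

#' Preferred display label for a term
#'
#' Recommended values carry the display label observed in the mined rules; for
#' presentation, ontology-based values are shown with the preferred label the
#' lexicon defines for the URI. Text-mode values (no URI) are returned as-is,
#' as are URIs the lexicon does not know (falling back to the supplied label).
#'
#' @inheritParams lookup_terms
#' @param uri Character vector of term URIs (may contain `NA`).
#' @param label Character vector of fallback labels, recycled to `uri`.
#' @return Character vector of display labels.
#' @export
display_label <- function(lexicon, uri, label = uri) {
  out <- rep_len(label, length(uri))
  if (is.null(lexicon)) return(out)
  hit <- match(uri, lexicon$entries$uri)
  found <- !is.na(hit)
  out[found] <- lexicon$entries$preferred_label[hit[found]]
  out
}

#' Format a recommendation score for display
#'
#' Scores are fractions in machine-facing output; at the presentation layer
#' they are shown as percentages (0.28 becomes "28%").
#'
#' @param x Numeric vector of scores in \[0, 1\].
#' @param digits Decimal places of the percentage.
#' @return Character vector like `"28%"`.
#' @export
percent_score <- function(x, digits = 0) {
  paste0(formatC(100 * x, format = "f", digits = digits), "%")
}

#' Annotate a text-mode repository with ontology terms
#'
#' Replays the semantic-annotation step: every pair whose field label and
#' value label both resolve in the lexicon gains the corresponding URIs.
#' Pairs whose *value* label does not resolve are dropped from the instance
#' (an unannotatable value cannot take part in URI-level analysis); a *field*
#' label that does not resolve is a configuration error, because templates
#' have few fields and an unmapped field is a setup bug.
#'
#' @param instances A text-mode instance table.
#' @param lexicon An [annotation_lexicon()] covering all field labels.
#' @return An ontology-mode instance tibble (all remaining pairs carry URIs).
#' @export
annotate_instances <- function(instances, lexicon) {
  instances <- as_instances(instances)
  placeholder <- is.na(instances$field_label) & is.na(instances$value_label)
  pairs <- instances[!placeholder, , drop = FALSE]
  f <- lookup_terms(lexicon, pairs$field_label)
  if (any(is.na(f$uri))) {
    abort(paste0("field label not in lexicon: '",
                 pairs$field_label[which(is.na(f$uri))[1]], "'"))
  }
  v <- lookup_terms(lexicon, pairs$value_label)
  pairs$field_uri <- f$uri
  pairs$value_uri <- v$uri
  kept <- pairs[!is.na(pairs$value_uri), , drop = FALSE]
  # instances whose every value was unannotatable survive as empty instances
  emptied <- pairs[!pairs$instance_id %in% kept$instance_id, , drop = FALSE]
  emptied <- distinct(emptied, .data$instance_id, .keep_all = TRUE)
  emptied[, c("field_label", "field_uri", "value_label", "value_uri")] <-
    NA_character_
  as_instances(bind_rows(kept, emptied,
                         instances[placeholder, , drop = FALSE]))
}

#' Read and write mapping and lexicon files
#'
#' Mapping files are JSON lists of `{"a": uri, "b": uri}` objects; lexicon
#' files are JSON lists of `{"label", "uri", "preferredLabel"}` objects.
#'
#' @param path File path.
#' @return `read_mappings()`: a [term_mappings()]; `read_lexicon()`: an
#'   [annotation_lexicon()]. Writers return their input invisibly.
#' @export
read_mappings <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0) return(term_mappings(NULL))
  term_mappings(as_tibble(df))
}

#' @param mappings A [term_mappings()] object.
#' @rdname read_mappings
#' @export
write_mappings <- function(mappings, path) {
  jsonlite::write_json(mappings$pairs, path, dataframe = "rows", digits = NA)
  invisible(mappings)
}

#' @rdname read_mappings
#' @export
read_lexicon <- function(path) {
  df <- as_tibble(jsonlite::fromJSON(path))
  if ("preferredLabel" %in% names(df)) {
    df <- rename(df, preferred_label = "preferredLabel")
  }
  annotation_lexicon(df)
}

#' @param lexicon An [annotation_lexicon()] object.
#' @rdname read_mappings
#' @export
write_lexicon <- function(lexicon, path) {
  out <- lexicon$entries %>%
    select(label = "label", uri = "uri",
           preferredLabel = "preferred_label")
  jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
  invisible(lexicon)
}
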