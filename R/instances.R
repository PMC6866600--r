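#' Instance tables
#'
#' A metadata template is a set of named fields that users fill in; every
#' filled-in copy is a *template instance*: a set of field--value pairs in which
#' empty fields are simply omitted. `metarec` represents a repository of
#' instances as a long tibble with one row per field--value pair and the
#' columns:
#'
#' * `template_id` -- identifier of the template the instance instantiates,
#' * `instance_id` -- identifier of the instance (unique within the table),
#' * `field_label`, `field_uri` -- the field's display label and (optionally)
#'   the ontology-term URI it is annotated with (`NA` in plain-text mode),
#' * `value_label`, `value_uri` -- the entered value's label and optional URI.
#'
#' An instance that exists but has no populated fields is kept as a single
#' placeholder row whose four label/URI columns are all `NA`; such rows count
#' towards repository size but never towards transactions or rules.
#'
#' `as_instances()` validates (and lightly normalizes) a data frame into this
#' shape: labels are whitespace-trimmed, pairs whose value label is empty are
#' dropped (an empty value means the field was not populated), and a field
#' occurring twice within one instance is an error.
#'
#' @param x A data frame with the columns above (`field_uri`/`value_uri` may be
#'   missing and default to `NA`).
#' @return A tibble in the canonical instance layout.
#' @examples
#' as_instances(data.frame(
#'   template_id = "t1", instance_id = "i1",
#'   field_label = c("sex", "tissue"), value_label = c("male", "liver")
#' ))
#' @export
as_instances <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("template_id", "instance_id", "field_label", "value_label")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (!"field_uri" %in% names(x)) x$field_uri <- NA_character_
  if (!"value_uri" %in% names(x)) x$value_uri <- NA_character_
  x <- x %>%
    select("template_id", "instance_id", "field_label", "field_uri",
           "value_label", "value_uri") %>%
    mutate(
      template_id = trimws(as.character(.data$template_id)),
      instance_id = trimws(as.character(.data$instance_id)),
      field_label = trimws(as.character(.data$field_label)),
      field_uri   = trimws(as.character(.data$field_uri)),
      value_label = trimws(as.character(.data$value_label)),
      value_uri   = trimws(as.character(.data$value_uri))
    )
  x$field_uri[!is.na(x$field_uri) & x$field_uri == ""] <- NA_character_
  x$value_uri[!is.na(x$value_uri) & x$value_uri == ""] <- NA_character_
  if (any(x$template_id == "" | is.na(x$template_id))) {
    abort("every instance must carry a non-empty template_id")
  }
  placeholder <- is.na(x$field_label) & is.na(x$value_label)
  pairs <- x[!placeholder, , drop = FALSE]
  if (any(is.na(pairs$field_label) | pairs$field_label == "")) {
    abort("field labels must be non-empty")
  }
  # an empty string value means the field was left unpopulated
  pairs <- pairs[!is.na(pairs$value_label) & pairs$value_label != "", ,
                 drop = FALSE]
  dup <- pairs %>%
    count(.data$instance_id, .data$field_label) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "duplicate field within one instance: ",
      paste0(dup$instance_id[1], " / ", dup$field_label[1])
    ))
  }
  # instances whose every pair was dropped become placeholders
  kept_ids <- unique(pairs$instance_id)
  empties <- x[placeholder, , drop = FALSE]
  lost <- setdiff(unique(x$instance_id), c(kept_ids, empties$instance_id))
  if (length(lost) > 0) {
    empties <- bind_rows(empties, tibble(
      template_id = x$template_id[match(lost, x$instance_id)],
      instance_id = lost,
      field_label = NA_character_, field_uri = NA_character_,
      value_label = NA_character_, value_uri = NA_character_
    ))
  }
  bind_rows(pairs, distinct(empties, .data$instance_id, .keep_all = TRUE))
}

#' Number of instances in an instance table
#'
#' Counts distinct instances, including empty placeholder instances. This is
#' the denominator used to normalize rule support into a frequency when
#' recommending without context.
#'
#' @param instances An instance table (see [as_instances()]).
#' @return Named integer vector: instances per `template_id`.
#' @export
n_instances <- function(instances) {
  tab <- instances %>%
    distinct(.data$template_id, .data$instance_id) %>%
    count(.data$template_id)
  setNames(tab$n, tab$template_id)
}

#' Read and write template-instance files
#'
#' Instance files are JSON with the layout
#' `{"templateId": str, "instances": [{"id": str, "pairs": [{"fieldLabel",
#' "fieldType", "fieldValueLabel", "fieldValueType"}]}]}`, where `fieldType`
#' and `fieldValueType` hold ontology-term URIs and may be `null`.
#'
#' In `"text"` mode URIs are read but play no role in matching. In
#' `"ontology"` mode pairs whose value carries no URI are dropped from the
#' instance: an unannotated value cannot participate in URI-level matching.
#'
#' @param path Path to an instance JSON file.
#' @param mode `"text"` or `"ontology"`.
#' @param prefixes Optional named character vector of URI prefixes
#'   (e.g. `c(obo = "http://purl.obolibrary.org/obo/")`); when supplied,
#'   prefixed URIs are expanded before any comparison.
#' @return `read_instances()`: an instance tibble. `write_instances()`: the
#'   input, invisibly.
#' @export
read_instances <- function(path, mode = c("text", "ontology"),
                           prefixes = NULL) {
  mode <- match.arg(mode)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("malformed instance file '", path, "': ",
                                     conditionMessage(e)))
  )
  if (is.null(doc$templateId) || !nzchar(doc$templateId)) {
    abort(paste0("instance file '", path, "' lacks a templateId"))
  }
  rows <- map(doc$instances, function(inst) {
    if (is.null(inst$id)) {
      abort(paste0("instance without an id in '", path, "'"))
    }
    pairs <- inst$pairs %||% list()
    if (length(pairs) == 0) {
      return(tibble(
        template_id = doc$templateId, instance_id = inst$id,
        field_label = NA_character_, field_uri = NA_character_,
        value_label = NA_character_, value_uri = NA_character_
      ))
    }
    bad <- which(!map_lgl(pairs, ~ !is.null(.x$fieldLabel) &&
                            !is.null(.x$fieldValueLabel)))
    if (length(bad) > 0) {
      abort(paste0("malformed pair in instance '", inst$id, "' of '", path,
                   "' (record ", bad[1], ")"))
    }
    tibble(
      template_id = doc$templateId,
      instance_id = inst$id,
      field_label = map_chr(pairs, "fieldLabel"),
      field_uri = map_chr(pairs, ~ .x$fieldType %||% NA_character_),
      value_label = map_chr(pairs, "fieldValueLabel"),
      value_uri = map_chr(pairs, ~ .x$fieldValueType %||% NA_character_)
    )
  })
  out <- as_instances(bind_rows(rows))
  if (!is.null(prefixes)) {
    out$field_uri <- expand_uris(out$field_uri, prefixes)
    out$value_uri <- expand_uris(out$value_uri, prefixes)
  }
  if (mode == "ontology") {
    placeholder <- is.na(out$field_label) & is.na(out$value_label)
    out <- out[placeholder | !is.na(out$value_uri), , drop = FALSE]
    out <- as_instances(out)
  }
  out
}

#' @param instances An instance table.
#' @rdname read_instances
#' @export
write_instances <- function(instances, path) {
  instances <- as_instances(instances)
  tids <- unique(instances$template_id)
  if (length(tids) != 1) {
    abort("write_instances() writes one template per file; split by template_id")
  }
  insts <- split(instances, factor(instances$instance_id,
                                   levels = unique(instances$instance_id)))
  body <- list(
    templateId = jsonlite::unbox(tids),
    instances = unname(map(insts, function(df) {
      pairs <- df[!is.na(df$field_label), , drop = FALSE]
      list(
        id = jsonlite::unbox(df$instance_id[1]),
        pairs = unname(pmap(
          list(pairs$field_label, pairs$field_uri,
               pairs$value_label, pairs$value_uri),
          function(fl, fu, vl, vu) {
            list(fieldLabel = jsonlite::unbox(fl),
                 fieldType = if (is.na(fu)) NULL else jsonlite::unbox(fu),
                 fieldValueLabel = jsonlite::unbox(vl),
                 fieldValueType = if (is.na(vu)) NULL else jsonlite::unbox(vu))
          }))
      )
    }))
  )
  jsonlite::write_json(body, path, null = "null", digits = NA,
                       pretty = TRUE)
  invisible(instances)
}

#' Expand prefixed ontology-term URIs
#'
#' Replaces `prefix:` heads by their namespace so that the same term written in
#' prefixed and full form compares equal. Unknown prefixes are left untouched.
#'
#' @param x Character vector of (possibly prefixed) URIs.
#' @param prefixes Named character vector mapping prefix to namespace.
#' @return Character vector of expanded URIs.
#' @examples
#' expand_uris("obo:DOID_2043", default_prefixes())
#' @export
expand_uris <- function(x, prefixes = default_prefixes()) {
  if (length(prefixes) == 0) return(x)
  for (p in names(prefixes)) {
    hit <- !is.na(x) & startsWith(x, paste0(p, ":"))
    x[hit] <- paste0(prefixes[[p]], substring(x[hit], nchar(p) + 2L))
  }
  x
}

#' @rdname expand_uris
#' @export
default_prefixes <- function() {
  c(obo = "http://purl.obolibrary.org/obo/",
    efo = "http://www.ebi.ac.uk/efo/",
    ncit = "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#")
}

#' Build a context from entered field--value pairs
#'
#' The *context* is the set of field--value pairs the user has already entered
#' in the instance being completed. `as_context()` accepts either a data frame
#' in the instance-pair layout or a named character vector
#' (`c(disease = "meningitis")`) and returns a context tibble with the columns
#' `field_label`, `field_uri`, `value_label`, `value_uri`.
#'
#' @param x Named character vector or data frame of pairs; `NULL` or an empty
#'   vector gives the empty context.
#' @return A context tibble (possibly with zero rows).
#' @examples
#' as_context(c(disease = "meningitis"))
#' @export
as_context <- function(x = NULL) {
  empty <- tibble(field_label = character(), field_uri = character(),
                  value_label = character(), value_uri = character())
  if (is.null(x) || (is.atomic(x) && length(x) == 0)) return(empty)
  if (is.data.frame(x)) {
    x <- as_tibble(x)
    if (!"field_uri" %in% names(x)) x$field_uri <- NA_character_
    if (!"value_uri" %in% names(x)) x$value_uri <- NA_character_
    ctx <- x %>%
      select("field_label", "field_uri", "value_label", "value_uri") %>%
      mutate(field_label = trimws(.data$field_label),
             value_label = trimws(.data$value_label))
  } else {
    if (is.null(names(x)) || any(names(x) == "")) {
      abort("a context vector must be fully named: c(field = \"value\")")
    }
    ctx <- tibble(field_label = trimws(names(x)), field_uri = NA_character_,
                  value_label = trimws(unname(x)), value_uri = NA_character_)
  }
  if (anyDuplicated(ctx$field_label)) {
    abort("a context may not contain the same field twice")
  }
  ctx
}

#' Six-instance example repository
#'
#' A small plain-text repository of six instances of an 'Experiment' template
#' with the fields sex, tissue and disease. It is the worked example used
#' throughout the documentation: three brain/meningitis instances, three liver
#' instances with cirrhosis or liver cancer.
#'
#' @return An instance tibble with 6 instances (16 pairs).
#' @examples
#' example_instances()
#' @export
example_instances <- function() {
  rows <- list(
    c("I1", "sex", "male"), c("I1", "tissue", "brain"),
    c("I1", "disease", "meningitis"),
    c("I2", "sex", "female"), c("I2", "tissue", "brain"),
    c("I2", "disease", "meningitis"),
    c("I3", "tissue", "liver"), c("I3", "disease", "cirrhosis"),
    c("I4", "sex", "male"), c("I4", "tissue", "liver"),
    c("I4", "disease", "liver cancer"),
    c("I5", "tissue", "liver"), c("I5", "disease", "liver cancer"),
    c("I6", "sex", "male"), c("I6", "tissue", "brain"),
    c("I6", "disease", "meningitis")
  )
  as_instances(tibble(
    template_id = "experiment",
    instance_id = map_chr(rows, 1),
    field_label = map_chr(rows, 2),
    value_label = map_chr(rows, 3)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
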