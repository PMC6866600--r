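#' Read and write rule files
#'
#' Rules are serialized as a single JSON object carrying the mining
#' parameters, the per-template repository sizes (needed to score
#' recommendations when the context is empty) and one object per rule. Each
#' rule object holds the antecedent pair list, the single consequent pair, the
#' support, the confidence and the source template identifier; each pair is
#' written as `{"fieldLabel", "fieldType", "fieldTypeMappings",
#' "fieldValueLabel", "fieldValueType", "fieldValueMappings"}`, where the
#' `*Mappings` arrays list the equivalent ontology terms materialized from the
#' mapping repository at write time.
#'
#' `read_rules()` rebuilds the canonical item keys; equivalences are taken
#' from the `mappings` argument when given, otherwise reconstructed from the
#' `*Mappings` arrays stored in the file.
#'
#' @param rules A `rule_tbl` from [mine_rules()].
#' @param path File path.
#' @param mappings Optional [term_mappings()]; see Details.
#' @return `read_rules()`: a `rule_tbl`. `write_rules()`: input, invisibly.
#' @export
write_rules <- function(rules, path, mappings = NULL) {
  p <- attr(rules, "params")
  ni <- attr(rules, "n_instances")
  pair_obj <- function(fl, fu, vl, vu) {
    eq <- function(uri) {
      if (is.null(mappings) || is.na(uri)) return(list())
      as.list(setdiff(equivalent_terms(mappings, uri), uri))
    }
    list(fieldLabel = jsonlite::unbox(fl),
         fieldType = if (is.na(fu)) NULL else jsonlite::unbox(fu),
         fieldTypeMappings = eq(fu),
         fieldValueLabel = jsonlite::unbox(vl),
         fieldValueType = if (is.na(vu)) NULL else jsonlite::unbox(vu),
         fieldValueMappings = eq(vu))
  }
  body <- list(
    mode = jsonlite::unbox(p$mode),
    minSupportCount = jsonlite::unbox(p$min_support),
    minConfidence = jsonlite::unbox(p$min_confidence),
    nInstances = as.list(setNames(as.integer(ni), names(ni))),
    rules = map(seq_len(nrow(rules)), function(i) {
      a <- rules$antecedent[[i]]
      list(
        antecedent = unname(pmap(
          list(a$field_label, a$field_uri, a$value_label, a$value_uri),
          pair_obj)),
        consequent = pair_obj(rules$consequent_field_label[i],
                              rules$consequent_field_uri[i],
                              rules$consequent_value_label[i],
                              rules$consequent_value_uri[i]),
        support = jsonlite::unbox(as.integer(rules$support[i])),
        confidence = jsonlite::unbox(rules$confidence[i]),
        templateId = jsonlite::unbox(rules$template_id[i])
      )
    })
  )
  jsonlite::write_json(body, path, null = "null", digits = NA, pretty = TRUE)
  invisible(rules)
}

#' @rdname write_rules
#' @export
read_rules <- function(path, mappings = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  get_pair <- function(p) {
    tibble(field_label = p$fieldLabel,
           field_uri = p$fieldType %||% NA_character_,
           value_label = p$fieldValueLabel,
           value_uri = p$fieldValueType %||% NA_character_)
  }
  if (is.null(mappings)) {
    # reconstruct equivalences from the materialized mapping arrays
    pairs <- list()
    for (r in doc$rules) {
      for (p in c(r$antecedent, list(r$consequent))) {
        sides <- list(c("fieldType", "fieldTypeMappings"),
                      c("fieldValueType", "fieldValueMappings"))
        for (side in sides) {
          uri <- p[[side[1]]]
          eqs <- p[[side[2]]]
          if (!is.null(uri) && length(eqs) > 0) {
            pairs[[length(pairs) + 1]] <-
              tibble(a = uri, b = unlist(eqs))
          }
        }
      }
    }
    mappings <- if (length(pairs) > 0) term_mappings(bind_rows(pairs))
                else term_mappings(NULL)
  }
  mode <- doc$mode %||% "text"
  rows <- map(doc$rules, function(r) {
    ant <- bind_rows(map(r$antecedent, get_pair))
    con <- get_pair(r$consequent)
    tibble(
      template_id = r$templateId,
      antecedent = list(ant),
      antecedent_keys = list(sort(pair_key(ant, mappings, mode))),
      consequent_key = pair_key(con, mappings, mode),
      consequent_field_label = con$field_label,
      consequent_field_uri = con$field_uri,
      consequent_value_label = con$value_label,
      consequent_value_uri = con$value_uri,
      consequent_field_key = field_key(con, mappings, mode),
      consequent_value_key = value_key(con, mappings, mode),
      support = as.integer(r$support),
      confidence = as.numeric(r$confidence)
    )
  })
  out <- bind_rows(rows)
  out$rule_id <- seq_len(nrow(out))
  out <- select(out, "rule_id", dplyr::everything())
  ni <- unlist(doc$nInstances)
  new_rule_tbl(out,
               params = list(min_support = doc$minSupportCount,
                             min_confidence = doc$minConfidence,
                             max_antecedent = Inf, mode = mode),
               n_instances = setNames(as.integer(ni), names(ni)))
}
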