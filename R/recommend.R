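# normalize a target-field spec (bare string, or list/data frame with
# field_label/field_uri) to its canonical matching key
as_target_key <- function(target_field, mappings, mode) {
  if (is.list(target_field) || is.data.frame(target_field)) {
    label <- target_field$field_label %||% target_field$label
    uri <- target_field$field_uri %||% target_field$uri %||% label
  } else {
    stopifnot(is.character(target_field), length(target_field) == 1)
    label <- target_field
    uri <- target_field
  }
  if (mode == "text") trimws(label) else
    term_representative(mappings, trimws(uri))
}

#' Select the rules that can produce values for a target field
#'
#' Returns the subset of rules whose consequent field matches the target
#' field: by label equality in text mode, by URI equivalence class in
#' ontology mode. The consequents of the selected rules are the candidate
#' values for the recommendation.
#'
#' @param rules A `rule_tbl` from [mine_rules()] or [read_rules()].
#' @param target_field The field being filled in: a label (text mode) or a
#'   term URI (ontology mode); alternatively a list with `field_label` /
#'   `field_uri`.
#' @param mappings Optional [term_mappings()] for ontology-mode matching.
#' @return The matching rows of `rules`.
#' @examples
#' rules <- mine_rules(example_instances(), min_support = 1,
#'                     min_confidence = 0.5)
#' select_rules(rules, "tissue")
#' @export
select_rules <- function(rules, target_field, mappings = NULL) {
  mode <- attr(rules, "params")$mode
  tkey <- as_target_key(target_field, mappings, mode)
  rules[rules$consequent_field_key == tkey, , drop = FALSE]
}

#' Context-matching score of rules against a context
#'
#' The Jaccard index (intersection over union) between each rule's antecedent
#' and the context, with pair membership decided at the canonical-key level
#' (label equality in text mode, URI-class equality in ontology mode). A score
#' of 1 means the antecedent matches the entered pairs exactly; 0 means no
#' overlap.
#'
#' @inheritParams select_rules
#' @param context Entered field--value pairs (see [as_context()]); must be
#'   non-empty.
#' @return Numeric vector in \[0, 1\], one score per rule row.
#' @examples
#' rules <- mine_rules(example_instances(), min_support = 1,
#'                     min_confidence = 0.5)
#' sel <- select_rules(rules, "tissue")
#' context_match_scores(sel, c(disease = "meningitis"))
#' @export
context_match_scores <- function(rules, context, mappings = NULL) {
  mode <- attr(rules, "params")$mode
  ctx <- as_context(context)
  if (nrow(ctx) == 0) abort("the context must contain at least one pair")
  ctx_keys <- pair_key(ctx, mappings, mode)
  jaccard_to_context(rules$antecedent_keys, ctx_keys)
}

jaccard_to_context <- function(antecedent_keys, ctx_keys) {
  inter <- map_int(antecedent_keys, ~ sum(.x %in% ctx_keys))
  union <- lengths(antecedent_keys) + length(ctx_keys) - inter
  inter / union
}

#' Recommend values for a target field
#'
#' The core recommendation function. Rules whose consequent matches the
#' target field are selected; when a context is given, each candidate value is
#' scored as the Jaccard context-matching score of its rule times the rule's
#' confidence. When the context is empty, the score is the rule support
#' normalized by the size of the rule's source repository, i.e. the frequency
#' of the value. Candidates with score 0 are discarded; duplicate values keep
#' their highest-scoring rule; ties in score are broken by support, residual
#' ties by value label.
#'
#' Context pairs for fields equivalent to the target field are ignored (the
#' target field cannot already be filled in).
#'
#' @inheritParams select_rules
#' @param context Entered pairs ([as_context()]); `NULL` or empty for the
#'   no-context case.
#' @param cutoff Discard candidates with recommendation score below this
#'   value (default 0: keep every positive score).
#' @param top_n Return at most this many values.
#' @return A tibble of class `recommendation_tbl`, one row per recommended
#'   value, ordered best-first: `value_label`, `value_uri`,
#'   `recommendation_score`, `context_match`, `confidence`, `support`,
#'   `rule_id`, `template_id`.
#' @examples
#' rules <- mine_rules(example_instances(), min_support = 1,
#'                     min_confidence = 0.5)
#' recommend_values(rules, "tissue", context = c(disease = "meningitis"))
#' @export
recommend_values <- function(rules, target_field, context = NULL,
                             mappings = NULL, cutoff = 0, top_n = Inf) {
  mode <- attr(rules, "params")$mode
  tkey <- as_target_key(target_field, mappings, mode)
  ctx <- as_context(context)
  if (nrow(ctx) > 0) {
    ctx <- ctx[field_key(ctx, mappings, mode) != tkey, , drop = FALSE]
  }
  sel <- rules[rules$consequent_field_key == tkey, , drop = FALSE]
  empty <- tibble(value_label = character(), value_uri = character(),
                  recommendation_score = double(), context_match = double(),
                  confidence = double(), support = integer(),
                  rule_id = integer(), template_id = character())
  if (nrow(sel) == 0) {
    return(new_recommendation_tbl(empty, target_field, mode))
  }
  if (nrow(ctx) == 0) {
    ni <- attr(rules, "n_instances")
    score <- sel$support / unname(ni[sel$template_id])
    cm <- rep(NA_real_, nrow(sel))
  } else {
    ctx_keys <- pair_key(ctx, mappings, mode)
    cm <- jaccard_to_context(sel$antecedent_keys, ctx_keys)
    score <- cm * sel$confidence
  }
  cand <- tibble(
    value_key = sel$consequent_value_key,
    value_label = sel$consequent_value_label,
    value_uri = sel$consequent_value_uri,
    recommendation_score = score,
    context_match = cm,
    confidence = sel$confidence,
    support = as.integer(sel$support),
    rule_id = sel$rule_id,
    template_id = sel$template_id
  )
  out <- rank_candidates(cand)
  out <- out[out$recommendation_score >= cutoff, , drop = FALSE]
  if (is.finite(top_n)) out <- slice_head(out, n = top_n)
  new_recommendation_tbl(select(out, -"value_key"), target_field, mode)
}

# shared ranking: drop zero scores, collapse duplicate values to their
# best-scoring rule, order by score then support then label
rank_candidates <- function(cand) {
  cand <- cand[cand$recommendation_score > 0, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  cand <- cand %>%
    arrange(desc(.data$recommendation_score), desc(.data$support),
            .data$value_label) %>%
    group_by(.data$value_key) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(desc(.data$recommendation_score), desc(.data$support),
            .data$value_label)
  cand
}

new_recommendation_tbl <- function(df, target_field, mode) {
  structure(as_tibble(df), target_field = target_field, mode = mode,
            class = c("recommendation_tbl", class(as_tibble(df))))
}

#' @export
print.recommendation_tbl <- function(x, ...) {
  tf <- attr(x, "target_field")
  if (is.list(tf)) tf <- tf$field_label %||% tf$field_uri
  cat("<recommendations> target field: ", tf, "\n", sep = "")
  if (nrow(x) == 0) {
    cat("(no recommended values)\n")
  } else {
    disp <- mutate(as_tibble(x),
                   score = percent_score(.data$recommendation_score))
    print(select(disp, "value_label", "score", "support", "confidence"), ...)
  }
  invisible(x)
}
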