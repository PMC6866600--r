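#' Encode instances as transactions
#'
#' Each instance with at least one populated pair becomes one transaction
#' whose items are canonically encoded field--value pairs: in text mode the
#' item key is built from the trimmed field and value labels; in ontology mode
#' from the class representatives of the field and value URIs, so that
#' equivalent URIs from different ontologies map to one item.
#'
#' @param instances An instance table ([as_instances()]).
#' @param mappings Optional [term_mappings()] used for canonicalization in
#'   ontology mode.
#' @param mode `"text"` or `"ontology"`.
#' @return The pair rows of `instances` with added `item`, `field_key` and
#'   `value_key` columns; empty instances contribute no rows.
#' @export
as_transactions <- function(instances, mappings = NULL,
                            mode = c("text", "ontology")) {
  mode <- match.arg(mode)
  instances <- as_instances(instances)
  pairs <- instances[!is.na(instances$field_label), , drop = FALSE]
  pairs$field_key <- field_key(pairs, mappings, mode)
  pairs$value_key <- value_key(pairs, mappings, mode)
  pairs$item <- paste0(pairs$field_key, "\x1f", pairs$value_key)
  dup <- pairs %>% count(.data$instance_id, .data$field_key) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("instance '", dup$instance_id[1],
                 "' has two pairs for one canonical field"))
  }
  pairs
}

#' Mine single-consequent association rules
#'
#' Extracts all association rules `X -> (f, v)` whose joint support (number of
#' instances containing every pair of the rule) reaches `min_support` and
#' whose confidence (joint support divided by antecedent support) reaches
#' `min_confidence`, using a level-wise Apriori search over frequent itemsets.
#' Only rules with exactly one field--value pair in the consequent are
#' produced, because recommendations target one field at a time; no field
#' occurs on both sides of a rule.
#'
#' Support is an absolute instance count, not a fraction. Rules are mined per
#' template (instances of different templates are not pooled unless
#' `pool_templates = TRUE`); cross-template reuse happens later, at matching
#' time, through the mapping repository. Rules are returned ordered by
#' confidence, then support (both decreasing), then a canonical antecedent key
#' for reproducibility.
#'
#' The defaults (`min_support = 5`, `min_confidence = 0.3`) are the settings
#' used for repository-scale corpora; small worked examples typically use
#' `min_support = 1`, `min_confidence = 0.5`.
#'
#' @inheritParams as_transactions
#' @param min_support Minimum number of supporting instances (>= 1).
#' @param min_confidence Minimum rule confidence in (0, 1].
#' @param max_antecedent Maximum antecedent size; `NULL` means unbounded
#'   (antecedents can never exceed the number of fields minus one).
#' @param pool_templates Mine a single rule set over all templates instead of
#'   one per template.
#' @return A `rule_tbl`: a tibble with one row per rule (`rule_id`,
#'   `template_id`, `antecedent` list-column of pair tibbles, consequent
#'   columns, `support`, `confidence`) carrying the mining parameters and the
#'   per-template repository sizes as attributes.
#' @examples
#' rules <- mine_rules(example_instances(), min_support = 1,
#'                     min_confidence = 0.5)
#' tidy(rules)
#' @export
mine_rules <- function(instances, mappings = NULL,
                       mode = c("text", "ontology"),
                       min_support = 5L, min_confidence = 0.3,
                       max_antecedent = NULL, pool_templates = FALSE) {
  mode <- match.arg(mode)
  stopifnot(min_support >= 1, min_confidence > 0, min_confidence <= 1)
  instances <- as_instances(instances)
  n_by_template <- n_instances(instances)
  tx <- as_transactions(instances, mappings, mode)
  if (pool_templates) {
    groups <- list(pooled = tx)
    n_by_template <- c(pooled = sum(n_by_template))
  } else {
    groups <- split(tx, tx$template_id)
  }
  max_ant <- if (is.null(max_antecedent)) Inf else max_antecedent

  rules <- imap(groups, function(g, tid) {
    trs <- split(g$item, g$instance_id)
    mined <- apriori_rules(trs, min_support, min_confidence, max_ant)
    if (nrow(mined) == 0) return(mined)
    mined$template_id <- if (pool_templates) "pooled" else tid
    dict <- g %>%
      distinct(.data$item, .keep_all = TRUE) %>%
      select("item", "field_label", "field_uri", "value_label", "value_uri",
             "field_key", "value_key")
    decorate_rules(mined, dict)
  })
  rules <- bind_rows(rules)
  if (nrow(rules) > 0) {
    ant_sort_key <- map_chr(rules$antecedent_keys, paste, collapse = "|")
    rules <- rules[order(-rules$confidence, -rules$support,
                         ant_sort_key, rules$consequent_key), , drop = FALSE]
    rules$rule_id <- seq_len(nrow(rules))
    rules <- select(rules, "rule_id", dplyr::everything())
  }
  new_rule_tbl(rules,
               params = list(min_support = as.integer(min_support),
                             min_confidence = min_confidence,
                             max_antecedent = max_antecedent,
                             mode = mode),
               n_instances = n_by_template)
}

new_rule_tbl <- function(df, params, n_instances) {
  structure(as_tibble(df), params = params, n_instances = n_instances,
            class = c("rule_tbl", class(as_tibble(df))))
}

empty_rules <- function() {
  tibble(antecedent_keys = list(), consequent_key = character(),
         support = integer(), confidence = double())
}

# attach labels/URIs from the item dictionary to mined key-level rules
decorate_rules <- function(mined, dict) {
  lk <- function(keys, col) dict[[col]][match(keys, dict$item)]
  mined$antecedent <- map(mined$antecedent_keys, function(ks) {
    tibble(field_label = lk(ks, "field_label"),
           field_uri = lk(ks, "field_uri"),
           value_label = lk(ks, "value_label"),
           value_uri = lk(ks, "value_uri"))
  })
  hit <- match(mined$consequent_key, dict$item)
  mined$consequent_field_label <- dict$field_label[hit]
  mined$consequent_field_uri <- dict$field_uri[hit]
  mined$consequent_value_label <- dict$value_label[hit]
  mined$consequent_value_uri <- dict$value_uri[hit]
  mined$consequent_field_key <- dict$field_key[hit]
  mined$consequent_value_key <- dict$value_key[hit]
  mined
}

# level-wise Apriori over transactions given as a list of item-key vectors;
# returns key-level rules (antecedent_keys, consequent_key, support, confidence)
apriori_rules <- function(transactions, min_support, min_confidence,
                          max_antecedent) {
  transactions <- keep(transactions, ~ length(.x) > 0)
  n_tr <- length(transactions)
  if (n_tr == 0 || min_support > n_tr) return(empty_rules())
  items <- sort(unique(unlist(transactions, use.names = FALSE)))
  m <- matrix(FALSE, nrow = n_tr, ncol = length(items))
  for (i in seq_len(n_tr)) m[i, match(transactions[[i]], items)] <- TRUE

  supp_env <- new.env(parent = emptyenv(), size = 1024L)
  set_key <- function(idx) paste(idx, collapse = ",")
  itemset_support <- function(idx) {
    cnt <- m[, idx[1]]
    for (j in idx[-1]) cnt <- cnt & m[, j]
    sum(cnt)
  }

  supp1 <- colSums(m)
  f1 <- which(supp1 >= min_support)
  for (i in f1) assign(set_key(i), supp1[i], envir = supp_env)
  frequent <- list(matrix(f1, ncol = 1))
  max_size <- min(length(items), max_antecedent + 1)

  k <- 2
  while (k <= max_size && nrow(frequent[[k - 1]]) >= 2) {
    cand <- apriori_candidates(frequent[[k - 1]])
    if (is.null(cand)) break
    # prune candidates with an infrequent (k-1)-subset
    ok <- map_lgl(seq_len(nrow(cand)), function(r) {
      all(map_lgl(seq_len(k), function(d) {
        !is.null(supp_env[[set_key(cand[r, -d])]])
      }))
    })
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    supp <- map_int(seq_len(nrow(cand)),
                    function(r) as.integer(itemset_support(cand[r, ])))
    hit <- supp >= min_support
    cand <- cand[hit, , drop = FALSE]
    supp <- supp[hit]
    if (nrow(cand) == 0) break
    for (r in seq_len(nrow(cand))) {
      assign(set_key(cand[r, ]), supp[r], envir = supp_env)
    }
    frequent[[k]] <- cand
    k <- k + 1
  }

  out <- list()
  for (size in seq_along(frequent)[-1]) {
    sets <- frequent[[size]]
    for (r in seq_len(nrow(sets))) {
      s <- sets[r, ]
      supp_s <- supp_env[[set_key(s)]]
      for (pos in seq_len(size)) {
        ant <- s[-pos]
        if (length(ant) > max_antecedent) next
        conf <- supp_s / supp_env[[set_key(ant)]]
        if (conf >= min_confidence - 1e-12) {
          out[[length(out) + 1]] <- list(
            antecedent_keys = list(items[ant]),
            consequent_key = items[s[pos]],
            support = as.integer(supp_s),
            confidence = conf
          )
        }
      }
    }
  }
  if (length(out) == 0) return(empty_rules())
  tibble(
    antecedent_keys = map(out, ~ .x$antecedent_keys[[1]]),
    consequent_key = map_chr(out, "consequent_key"),
    support = map_int(out, "support"),
    confidence = map_dbl(out, "confidence")
  )
}

# join frequent (k-1)-itemsets sharing a common prefix into k-candidates
apriori_candidates <- function(freq) {
  k1 <- ncol(freq)
  ord <- do.call(order, as.data.frame(freq))
  freq <- freq[ord, , drop = FALSE]
  prefix <- if (k1 == 1) rep("", nrow(freq)) else
    apply(freq[, -k1, drop = FALSE], 1, paste, collapse = ",")
  out <- list()
  for (ix in split(seq_len(nrow(freq)), prefix)) {
    if (length(ix) < 2) next
    last <- sort(freq[ix, k1])
    base <- freq[ix[1], -k1]
    cmb <- combn(last, 2)
    for (j in seq_len(ncol(cmb))) {
      out[[length(out) + 1]] <- c(base, cmb[, j])
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Support and confidence of one rule
#'
#' Counts, over the given repository, the instances containing every pair of
#' the rule (support) and divides by the instances containing the antecedent
#' pairs (confidence).
#'
#' @inheritParams as_transactions
#' @param antecedent,consequent Data frames of field--value pairs (see
#'   [as_context()] for accepted forms); the consequent must be a single pair.
#' @return One-row tibble with `support` and `confidence`. An antecedent
#'   contained in no instance has undefined confidence, returned as `NA` with
#'   a warning (such a rule cannot exist).
#' @examples
#' rule_metrics(example_instances(),
#'              antecedent = c(sex = "male", disease = "meningitis"),
#'              consequent = c(tissue = "brain"))
#' @export
rule_metrics <- function(instances, antecedent, consequent, mappings = NULL,
                         mode = c("text", "ontology")) {
  mode <- match.arg(mode)
  ant <- as_context(antecedent)
  con <- as_context(consequent)
  stopifnot(nrow(ant) >= 1, nrow(con) == 1)
  tx <- as_transactions(instances, mappings, mode)
  trs <- split(tx$item, tx$instance_id)
  ant_keys <- pair_key(ant, mappings, mode)
  all_keys <- c(ant_keys, pair_key(con, mappings, mode))
  n_ant <- sum(map_lgl(trs, ~ all(ant_keys %in% .x)))
  n_all <- sum(map_lgl(trs, ~ all(all_keys %in% .x)))
  if (n_ant == 0) {
    warn("antecedent occurs in no instance; confidence is undefined")
    return(tibble(support = 0L, confidence = NA_real_))
  }
  tibble(support = as.integer(n_all), confidence = n_all / n_ant)
}

#' @export
print.rule_tbl <- function(x, ...) {
  p <- attr(x, "params")
  cat("<rule_tbl> ", nrow(x), " rules (min support ", p$min_support,
      ", min confidence ", p$min_confidence, ", ", p$mode, " mode)\n",
      sep = "")
  if (nrow(x) > 0) print(tidy(x), ...)
  invisible(x)
}

#' @rdname mine_rules
#' @param x A `rule_tbl`.
#' @param ... Unused.
#' @export
tidy.rule_tbl <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(rule_id = integer(), template_id = character(),
                  antecedent = character(), consequent_field = character(),
                  consequent_value = character(), support = integer(),
                  confidence = double()))
  }
  tibble(
    rule_id = x$rule_id,
    template_id = x$template_id,
    antecedent = map_chr(x$antecedent, function(a) {
      paste0(a$field_label, "=", a$value_label, collapse = " & ")
    }),
    consequent_field = x$consequent_field_label,
    consequent_value = x$consequent_value_label,
    support = x$support,
    confidence = x$confidence
  )
}

#' @rdname mine_rules
#' @export
glance.rule_tbl <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_rules = nrow(x),
    n_instances = sum(attr(x, "n_instances")),
    min_support = p$min_support,
    min_confidence = p$min_confidence,
    mode = p$mode,
    mean_confidence = if (nrow(x) > 0) mean(x$confidence) else NA_real_,
    max_antecedent_size = if (nrow(x) > 0)
      max(lengths(x$antecedent_keys)) else NA_integer_
  )
}
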