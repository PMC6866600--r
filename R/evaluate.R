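#' Split a repository into disjoint training and test sets
#'
#' Instances (not individual pairs) are assigned at random to the two sets;
#' the split is reproducible for a fixed seed and leaves every instance in
#' exactly one set.
#'
#' @param instances An instance table.
#' @param train_fraction Fraction of instances assigned to training
#'   (default 0.85).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return List with elements `train` and `test`.
#' @export
split_instances <- function(instances, train_fraction = 0.85, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  instances <- as_instances(instances)
  ids <- unique(instances$instance_id)
  if (length(ids) == 0) abort("cannot split an empty repository")
  n_train <- round(train_fraction * length(ids))
  train_ids <- with_local_seed(seed, sample(ids, n_train))
  list(train = instances[instances$instance_id %in% train_ids, , drop = FALSE],
       test = instances[!instances$instance_id %in% train_ids, , drop = FALSE])
}

# evaluate `expr` under `seed` without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Majority-class baseline
#'
#' The context-free reference predictor: it ranks the values observed for the
#' target field in the training repository by frequency, so it always suggests
#' the most frequent value first. In ontology mode frequencies are counted by
#' URI equivalence class, so synonymous values pool. Frequency ties are broken
#' by value label, ascending.
#'
#' @param train Training instance table.
#' @param target_field Field label (text mode) or term URI (ontology mode), or
#'   a list with `field_label` / `field_uri`.
#' @param mappings Optional [term_mappings()].
#' @param mode `"text"` or `"ontology"`.
#' @return Tibble `value_label`, `value_uri`, `n`, most frequent first; empty
#'   when the field was never observed.
#' @export
majority_baseline <- function(train, target_field, mappings = NULL,
                              mode = c("text", "ontology")) {
  mode <- match.arg(mode)
  tkey <- as_target_key(target_field, mappings, mode)
  tx <- as_transactions(train, mappings, mode)
  tx <- tx[tx$field_key == tkey, , drop = FALSE]
  if (nrow(tx) == 0) {
    return(tibble(value_label = character(), value_uri = character(),
                  n = integer()))
  }
  tx %>%
    group_by(.data$value_key) %>%
    summarise(value_label = .data$value_label[1],
              value_uri = .data$value_uri[1],
              n = dplyr::n(), .groups = "drop") %>%
    arrange(desc(.data$n), .data$value_label) %>%
    select("value_label", "value_uri", "n")
}

#' Reciprocal rank of the correct value in a ranked list
#'
#' 1 divided by the rank of the first listed value matching the expected one
#' (label equality in text mode, URI-class equality in ontology mode), and 0
#' when the expected value does not occur in the list at all -- the standard
#' convention, which penalizes non-coverage.
#'
#' @param values A ranked result: a [recommend_values()] /
#'   [majority_baseline()] tibble, or a character vector of value labels.
#' @param expected The true value: a string (label in text mode, URI in
#'   ontology mode) or a list with `value_label` / `value_uri`.
#' @inheritParams majority_baseline
#' @return A number in \[0, 1\].
#' @examples
#' reciprocal_rank(c("liver cancer", "cirrhosis"), "cirrhosis")
#' @export
reciprocal_rank <- function(values, expected, mappings = NULL,
                            mode = c("text", "ontology")) {
  mode <- match.arg(mode)
  if (is.character(values)) {
    values <- tibble(value_label = values, value_uri = values)
  }
  if (is.list(expected) && !is.data.frame(expected)) {
    elab <- expected$value_label %||% expected$label
    euri <- expected$value_uri %||% expected$uri %||% elab
  } else {
    elab <- expected
    euri <- expected
  }
  ekey <- if (mode == "text") trimws(elab) else
    term_representative(mappings, trimws(euri))
  vkeys <- if (mode == "text") trimws(values$value_label) else
    term_representative(mappings, trimws(values$value_uri))
  pos <- match(ekey, vkeys)
  if (is.na(pos)) 0 else 1 / pos
}

#' Enumerate evaluation contexts for one instance
#'
#' For a test instance with `p` populated evaluation fields besides the target,
#' every subset of those fields of size 0 to `min(p, max_context_size)` yields
#' one context, so a full sweep runs `sum(choose(p, 0:p))` executions per
#' target.
#'
#' @param instance The pair rows of a single instance.
#' @param target_field The field being predicted (excluded from all contexts).
#' @param fields Optional restriction of context fields to these labels.
#' @param max_context_size Largest context size to enumerate.
#' @inheritParams majority_baseline
#' @return List of context tibbles, smallest first; the first element is the
#'   empty context.
#' @export
enumerate_contexts <- function(instance, target_field, fields = NULL,
                               max_context_size = Inf, mappings = NULL,
                               mode = c("text", "ontology")) {
  mode <- match.arg(mode)
  instance <- as_instances(instance)
  pairs <- instance[!is.na(instance$field_label), , drop = FALSE]
  if (!is.null(fields)) {
    pairs <- pairs[pairs$field_label %in% fields, , drop = FALSE]
  }
  tkey <- as_target_key(target_field, mappings, mode)
  pairs <- pairs[field_key(pairs, mappings, mode) != tkey, , drop = FALSE]
  p <- nrow(pairs)
  out <- list(as_context(NULL))
  for (size in seq_len(min(p, max_context_size))) {
    for (j in seq_len(ncol(combn(p, size)))) {
      idx <- combn(p, size)[, j]
      out[[length(out) + 1]] <- as_context(pairs[idx, , drop = FALSE])
    }
  }
  out
}

#' Evaluate the recommender against the majority baseline
#'
#' Runs the train/test protocol: rules are mined from the training repository;
#' then, for every test instance, every target field under test with a
#' ground-truth value, and every enumerated context (all subsets of the other
#' populated evaluation fields up to `max_context_size`), the reciprocal rank
#' of the true value is computed for the rule-based recommender and for the
#' context-free majority baseline. Results are aggregated as mean reciprocal
#' rank (MRR) per method, field and context size.
#'
#' The empty-context executions use the recommender's support-normalized
#' scoring path and populate the context-size-0 cell. In ontology mode the
#' ground truth is matched by URI equivalence class, so any synonym of the
#' correct concept counts as correct; in text mode matching is exact-label.
#' The baseline ignores context, so its per-instance reciprocal rank is
#' constant across context sizes; it is entered into every cell the
#' recommender is evaluated in, making the two methods directly comparable.
#'
#' @param train,test Instance tables (disjoint; in a cross-template scenario
#'   they come from different templates and `mappings` aligns their fields
#'   and values).
#' @param fields Character vector of field labels, as they appear in the
#'   *test* instances, to predict and to use as context.
#' @inheritParams majority_baseline
#' @inheritParams mine_rules
#' @param max_context_size Largest context size in the sweep (default 5).
#' @param cutoff Recommendation-score cutoff passed to the recommender.
#' @param max_test_instances Evaluate at most this many test instances
#'   (sampled reproducibly with `seed`); `Inf` evaluates all.
#' @param seed Seed for the test-instance subsample.
#' @return A `recommender_eval` object; see [tidy.recommender_eval()],
#'   [glance.recommender_eval()], [mrr_by_context()] and
#'   [autoplot.recommender_eval()].
#' @export
evaluate_recommender <- function(train, test, fields,
                                 mode = c("text", "ontology"),
                                 mappings = NULL,
                                 min_support = 5L, min_confidence = 0.3,
                                 max_antecedent = NULL,
                                 max_context_size = 5L, cutoff = 0,
                                 max_test_instances = Inf, seed = NULL) {
  mode <- match.arg(mode)
  if (length(fields) == 0) abort("fields must name at least one field")
  train <- as_instances(train)
  test <- as_instances(test)
  if (nrow(train) == 0 || nrow(test) == 0) {
    abort("train and test repositories must both be non-empty")
  }
  rules <- mine_rules(train, mappings, mode, min_support, min_confidence,
                      max_antecedent)
  ni <- attr(rules, "n_instances")

  test_pairs <- test[!is.na(test$field_label), , drop = FALSE]
  test_pairs <- test_pairs[test_pairs$field_label %in% fields, , drop = FALSE]
  test_pairs$field_key <- field_key(test_pairs, mappings, mode)
  test_pairs$value_key <- value_key(test_pairs, mappings, mode)
  test_pairs$item <- paste0(test_pairs$field_key, "\x1f",
                            test_pairs$value_key)
  inst_ids <- unique(test_pairs$instance_id)
  if (is.finite(max_test_instances) &&
      length(inst_ids) > max_test_instances) {
    inst_ids <- with_local_seed(seed, sample(inst_ids, max_test_instances))
  }

  # per-field caches keyed by canonical field key
  sel_cache <- new.env(parent = emptyenv())
  base_cache <- new.env(parent = emptyenv())
  field_rules <- function(fkey) {
    if (is.null(sel_cache[[fkey]])) {
      sel_cache[[fkey]] <-
        rules[rules$consequent_field_key == fkey, , drop = FALSE]
    }
    sel_cache[[fkey]]
  }
  field_baseline_keys <- function(fkey, flabel, furi) {
    if (is.null(base_cache[[fkey]])) {
      tf <- list(field_label = flabel, field_uri = furi)
      b <- majority_baseline(train, tf, mappings, mode)
      base_cache[[fkey]] <- if (mode == "text") trimws(b$value_label) else
        term_representative(mappings, b$value_uri)
    }
    base_cache[[fkey]]
  }

  bitcount <- vapply(0:(2^min(max_context_size + 6, 20) - 1),
                     function(z) sum(intToBits(z) != 0), numeric(1))

  acc <- list()
  record <- function(method, field, size, rr) {
    key <- paste(method, field, size, sep = "\x1f")
    cur <- acc[[key]] %||% c(0, 0)
    acc[[key]] <<- c(cur[1] + rr, cur[2] + 1)
  }

  for (iid in inst_ids) {
    epairs <- test_pairs[test_pairs$instance_id == iid, , drop = FALSE]
    if (nrow(epairs) == 0) next
    for (t in seq_len(nrow(epairs))) {
      target <- epairs[t, ]
      truth_key <- target$value_key
      sel <- field_rules(target$field_key)
      base_keys <- field_baseline_keys(target$field_key, target$field_label,
                                       target$field_uri)
      pos <- match(truth_key, base_keys)
      rr_base <- if (is.na(pos)) 0 else 1 / pos

      ctx <- epairs[-t, , drop = FALSE]
      p <- nrow(ctx)
      # which context positions each rule's antecedent covers, as a bitmask
      masks <- if (nrow(sel) > 0) {
        map_int(sel$antecedent_keys, function(a) {
          as.integer(sum(2^(which(ctx$item %in% a) - 1)))
        })
      } else integer(0)
      ant_len <- lengths(sel$antecedent_keys)
      score_no_ctx <- if (nrow(sel) > 0)
        sel$support / unname(ni[sel$template_id]) else numeric(0)

      for (size in 0:min(p, max_context_size)) {
        subs <- if (size == 0) matrix(integer(0), nrow = 0, ncol = 1) else
          combn(p, size)
        for (j in seq_len(max(1, ncol(subs)))) {
          if (size == 0) {
            scores <- score_no_ctx
          } else {
            mask_s <- as.integer(sum(2^(subs[, j] - 1)))
            inter <- bitcount[bitwAnd(masks, mask_s) + 1]
            scores <- inter / (ant_len + size - inter) * sel$confidence
          }
          rr <- rr_of_scores(scores, sel$support, sel$consequent_value_key,
                             sel$consequent_value_label, truth_key, cutoff)
          record("recommender", target$field_label, size, rr)
          record("baseline", target$field_label, size, rr_base)
        }
      }
    }
  }

  cells <- tibble(key = names(acc)) %>%
    tidyr::separate_wider_delim("key", "\x1f",
                                names = c("method", "field", "context_size")) %>%
    mutate(context_size = as.integer(.data$context_size),
           n = unname(map_dbl(acc, 2)),
           mrr = unname(map_dbl(acc, 1)) / .data$n) %>%
    arrange(.data$method, .data$field, .data$context_size)
  structure(
    list(cells = cells,
         config = list(mode = mode, fields = fields,
                       min_support = min_support,
                       min_confidence = min_confidence,
                       max_context_size = max_context_size, cutoff = cutoff,
                       n_train = sum(n_instances(train)),
                       n_test = length(inst_ids)),
         rules = glance(rules)),
    class = "recommender_eval"
  )
}

# reciprocal rank of the truth among ranked, deduplicated candidate values;
# ordering matches rank_candidates(): score desc, support desc, label asc
rr_of_scores <- function(scores, support, value_keys, value_labels,
                         truth_key, cutoff = 0) {
  keep <- scores > 0 & scores >= cutoff
  if (!any(keep)) return(0)
  ord <- order(-scores[keep], -support[keep], value_labels[keep])
  vk <- value_keys[keep][ord]
  pos <- match(truth_key, vk[!duplicated(vk)])
  if (is.na(pos)) 0 else 1 / pos
}

#' @export
print.recommender_eval <- function(x, ...) {
  cat("<recommender_eval> mode:", x$config$mode,
      "| train:", x$config$n_train, "instances | test:", x$config$n_test,
      "instances\n")
  print(mrr_by_context(x), ...)
  invisible(x)
}

#' MRR aggregated over fields, by method and context size
#'
#' @param x A `recommender_eval` object.
#' @return Tibble `method`, `context_size`, `n` (executions), `mrr`.
#' @export
mrr_by_context <- function(x) {
  x$cells %>%
    group_by(.data$method, .data$context_size) %>%
    summarise(mrr = sum(.data$mrr * .data$n) / sum(.data$n),
              n = sum(.data$n), .groups = "drop") %>%
    select("method", "context_size", "n", "mrr")
}

#' @rdname evaluate_recommender
#' @param x A `recommender_eval` object.
#' @param ... Unused.
#' @export
tidy.recommender_eval <- function(x, ...) {
  x$cells
}

#' @rdname evaluate_recommender
#' @export
glance.recommender_eval <- function(x, ...) {
  x$cells %>%
    group_by(.data$method) %>%
    summarise(mrr = sum(.data$mrr * .data$n) / sum(.data$n),
              n_executions = sum(.data$n), .groups = "drop") %>%
    mutate(mode = x$config$mode, n_train = x$config$n_train,
           n_test = x$config$n_test)
}

#' Write an evaluation report to CSV
#'
#' One row per method x field x context-size cell, with execution counts and
#' MRR.
#'
#' @param x A `recommender_eval` object.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  utils::write.csv(as.data.frame(x$cells), path, row.names = FALSE)
  invisible(x)
}
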