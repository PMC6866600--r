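# Brute-force association-rule oracle: enumerates every (antecedent subset,
# single consequent) combination over the distinct items of a transaction
# list and filters by the thresholds with direct counting. Independent of the
# level-wise miner it is used to check.
oracle_rules <- function(transactions, min_support, min_confidence,
                         max_antecedent = Inf) {
  transactions <- Filter(length, transactions)
  items <- sort(unique(unlist(transactions, use.names = FALSE)))
  n <- length(items)
  stopifnot(n <= 14)
  supp_memo <- new.env(parent = emptyenv())
  supp <- function(keys) {
    k <- paste(keys, collapse = "|")
    if (is.null(supp_memo[[k]])) {
      supp_memo[[k]] <- sum(vapply(
        transactions, function(t) all(keys %in% t), logical(1)))
    }
    supp_memo[[k]]
  }
  rows <- list()
  if (n >= 2) {
    for (mask in seq_len(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(idx) < 2) next
      s <- supp(items[idx])
      if (s < min_support) next
      for (pos in seq_along(idx)) {
        ant <- items[idx[-pos]]
        if (length(ant) > max_antecedent) next
        conf <- s / supp(ant)
        if (conf >= min_confidence - 1e-12) {
          rows[[length(rows) + 1]] <- data.frame(
            antecedent = paste(sort(ant), collapse = "|"),
            consequent = items[idx[pos]],
            support = s, confidence = conf,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(antecedent = character(), consequent = character(),
                      support = integer(), confidence = double()))
  }
  out <- do.call(rbind, rows)
  out[order(out$antecedent, out$consequent), , drop = FALSE]
}

# canonical key-level view of a mined rule_tbl, comparable to oracle output
rules_canonical <- function(rules) {
  if (nrow(rules) == 0) {
    return(data.frame(antecedent = character(), consequent = character(),
                      support = integer(), confidence = double()))
  }
  out <- data.frame(
    antecedent = vapply(rules$antecedent_keys,
                        function(k) paste(sort(k), collapse = "|"), ""),
    consequent = rules$consequent_key,
    support = as.integer(rules$support),
    confidence = rules$confidence,
    stringsAsFactors = FALSE
  )
  out[order(out$antecedent, out$consequent), , drop = FALSE]
}

expect_same_rules <- function(mined, oracle) {
  rownames(mined) <- NULL
  rownames(oracle) <- NULL
  expect_equal(nrow(mined), nrow(oracle))
  expect_equal(mined$antecedent, oracle$antecedent)
  expect_equal(mined$consequent, oracle$consequent)
  expect_equal(mined$support, oracle$support)
  expect_equal(mined$confidence, oracle$confidence, tolerance = 1e-12)
}

# random small repository: up to 4 fields with up to 3 values each
random_repository <- function(n_instances = 8, n_fields = 4, n_values = 3) {
  rows <- list()
  for (i in seq_len(n_instances)) {
    flds <- sort(sample.int(n_fields, sample(1:n_fields, 1)))
    for (f in flds) {
      rows[[length(rows) + 1]] <- data.frame(
        template_id = "t", instance_id = paste0("i", i),
        field_label = paste0("f", f),
        value_label = paste0("v", f, "_", sample.int(n_values, 1)),
        stringsAsFactors = FALSE
      )
    }
  }
  as_instances(do.call(rbind, rows))
}

transactions_of <- function(instances, mappings = NULL, mode = "text") {
  tx <- as_transactions(instances, mappings, mode)
  split(tx$item, tx$instance_id)
}
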