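toy_rules <- function() {
  mine_rules(example_instances(), min_support = 1, min_confidence = 0.5)
}

test_that("rule selection keeps exactly the rules producing the target field", {
  rules <- toy_rules()
  sel <- select_rules(rules, "tissue")
  expect_true(all(sel$consequent_field_label == "tissue"))
  # at min confidence 0.67 the selected set is the eight documented rules
  sel67 <- select_rules(mine_rules(example_instances(), min_support = 1,
                                   min_confidence = 2 / 3), "tissue")
  expect_equal(nrow(sel67), 8)
  ants <- vapply(sel67$antecedent, function(a)
    paste(sort(paste0(a$field_label, "=", a$value_label)), collapse = " & "),
    "")
  expect_setequal(
    paste0(ants, " -> ", sel67$consequent_value_label),
    c("disease=meningitis -> brain",
      "disease=liver cancer -> liver",
      "disease=meningitis & sex=male -> brain",
      "sex=female -> brain",
      "disease=cirrhosis -> liver",
      "disease=liver cancer & sex=male -> liver",
      "disease=meningitis & sex=female -> brain",
      "sex=male -> brain")
  )
  expect_equal(nrow(select_rules(rules, "no such field")), 0)
})

test_that("context matching is intersection over union of pair sets", {
  sel <- select_rules(mine_rules(example_instances(), min_support = 1,
                                 min_confidence = 2 / 3), "tissue")
  scores <- context_match_scores(sel, c(disease = "meningitis"))
  expect_setequal(round(unique(scores), 3), c(1, 0.5, 0))
  expect_equal(sort(scores), sort(c(1, 0.5, 0.5, 0, 0, 0, 0, 0)))
  # an antecedent identical to the context scores 1
  one <- sel[vapply(sel$antecedent, function(a)
    identical(paste0(a$field_label, "=", a$value_label),
              "disease=meningitis"), logical(1)), ]
  expect_equal(context_match_scores(one, c(disease = "meningitis")), 1)
  # disjoint two-pair antecedent against one context pair: 0/3
  r9 <- sel[vapply(sel$antecedent, function(a)
    setequal(paste0(a$field_label, "=", a$value_label),
             c("sex=male", "disease=liver cancer")), logical(1)), ]
  expect_equal(context_match_scores(r9, c(disease = "meningitis")), 0)
})

test_that("the worked example recommends only 'brain' with score 1", {
  out <- recommend_values(toy_rules(), "tissue",
                          context = c(disease = "meningitis"))
  expect_equal(nrow(out), 1)
  expect_equal(out$value_label, "brain")
  expect_equal(out$recommendation_score, 1)
  expect_equal(out$context_match, 1)
  expect_equal(out$confidence, 1)
})

test_that("without context values are ranked by support frequency", {
  out <- recommend_values(toy_rules(), "tissue")
  expect_equal(out$value_label, c("brain", "liver"))
  expect_equal(out$recommendation_score, c(3 / 6, 2 / 6))
  # a cutoff prunes the tail; top_n truncates
  cut <- recommend_values(toy_rules(), "tissue", cutoff = 0.4)
  expect_equal(cut$value_label, "brain")
  top <- recommend_values(toy_rules(), "tissue", top_n = 1)
  expect_equal(nrow(top), 1)
})

test_that("zero-score candidates are discarded and duplicates keep the best rule", {
  out <- recommend_values(toy_rules(), "tissue",
                          context = c(disease = "liver cancer"))
  # 'liver' wins via its exact-match rule; 'brain' rules all score > 0 only
  # through partially matching antecedents
  expect_equal(out$value_label[1], "liver")
  expect_equal(out$recommendation_score[1], 1)
  expect_false(any(duplicated(out$value_label)))
  expect_true(all(out$recommendation_score > 0))
})

test_that("context pairs on the target field itself are ignored", {
  with_target <- recommend_values(
    toy_rules(), "tissue",
    context = c(disease = "meningitis", tissue = "liver"))
  without <- recommend_values(toy_rules(), "tissue",
                              context = c(disease = "meningitis"))
  expect_equal(as.data.frame(with_target), as.data.frame(without))
})

test_that("an unknown target field yields an empty recommendation list", {
  out <- recommend_values(toy_rules(), "karyotype",
                          context = c(disease = "meningitis"))
  expect_s3_class(out, "recommendation_tbl")
  expect_equal(nrow(out), 0)
})

test_that("cross-template recommendation resolves through the mapping repository", {
  sc <- example_scenarios()$cross_template
  rules <- mine_rules(sc$experiment_instances, mappings = sc$mappings,
                      mode = "ontology", min_support = 1,
                      min_confidence = 0.5)
  out <- recommend_values(rules, sc$target_field,
                          context = sc$assay_context,
                          mappings = sc$mappings)
  expect_equal(out$value_label[1], "pancreas")
  expect_equal(out$value_uri[1], "obo:UBERON_0001264")
  expect_equal(out$recommendation_score[1], 1)
  expect_equal(display_label(sc$lexicon, out$value_uri[1]), "pancreas")
})

test_that("recommendations are invariant under equivalent-URI relabelling", {
  sc <- example_scenarios()$cross_template
  m <- sc$mappings
  swap <- function(u) {
    vapply(u, function(x) {
      cls <- equivalent_terms(m, x)
      if (length(cls) > 1) setdiff(cls, x)[1] else x
    }, "", USE.NAMES = FALSE)
  }
  relab <- sc$experiment_instances
  relab$field_uri <- swap(relab$field_uri)
  relab$value_uri <- swap(relab$value_uri)
  r1 <- mine_rules(sc$experiment_instances, m, mode = "ontology",
                   min_support = 1, min_confidence = 0.5)
  r2 <- mine_rules(relab, m, mode = "ontology", min_support = 1,
                   min_confidence = 0.5)
  o1 <- recommend_values(r1, sc$target_field, context = sc$assay_context,
                         mappings = m)
  o2 <- recommend_values(r2, sc$target_field, context = sc$assay_context,
                         mappings = m)
  expect_equal(term_representative(m, o1$value_uri),
               term_representative(m, o2$value_uri))
  expect_equal(o1$recommendation_score, o2$recommendation_score)
  # relabelling the context instead changes nothing either
  ctx2 <- sc$assay_context
  ctx2$field_uri <- swap(ctx2$field_uri)
  ctx2$value_uri <- swap(ctx2$value_uri)
  o3 <- recommend_values(r1, sc$target_field, context = ctx2, mappings = m)
  expect_equal(o3$recommendation_score, o1$recommendation_score)
})

test_that("a planted deterministic dependency surfaces as the top recommendation", {
  set.seed(5)
  n <- 40
  diseases <- sample(c("meningitis", "hepatitis B"), n, replace = TRUE)
  tissue_of <- c(meningitis = "brain", `hepatitis B` = "liver")
  repo <- as_instances(data.frame(
    template_id = "t",
    instance_id = rep(paste0("i", 1:n), each = 2),
    field_label = rep(c("disease", "tissue"), n),
    value_label = as.vector(rbind(diseases, tissue_of[diseases]))
  ))
  rules <- mine_rules(repo, min_support = 2, min_confidence = 0.3)
  out <- recommend_values(rules, "tissue", context = c(disease = "meningitis"))
  expect_equal(out$value_label[1], "brain")
  expect_equal(out$recommendation_score[1], 1)
})

test_that("scoring agrees with a direct set-arithmetic oracle on random cases", {
  set.seed(21)
  for (i in 1:10) {
    repo <- random_repository(n_instances = 8)
    rules <- mine_rules(repo, min_support = 1, min_confidence = 0.3)
    tx <- as_transactions(repo)
    target <- sample(unique(tx$field_label), 1)
    ctx_rows <- tx[tx$field_label != target, ]
    if (nrow(ctx_rows) == 0) next
    pick <- ctx_rows[!duplicated(ctx_rows$field_label), ]
    pick <- pick[sample(nrow(pick), min(2, nrow(pick))), ]
    ctx <- setNames(pick$value_label, pick$field_label)
    out <- recommend_values(rules, target, context = ctx)

    # oracle: score every (rule, value) pair with direct set operations
    sel <- rules[rules$consequent_field_label == target, ]
    ctx_keys <- paste0(names(ctx), "\x1f", unname(ctx))
    best <- list()
    for (r in seq_len(nrow(sel))) {
      a <- sel$antecedent_keys[[r]]
      j <- length(intersect(a, ctx_keys)) / length(union(a, ctx_keys))
      s <- j * sel$confidence[r]
      v <- sel$consequent_value_label[r]
      if (s > 0 && (is.null(best[[v]]) || s > best[[v]]$s ||
                    (s == best[[v]]$s && sel$support[r] > best[[v]]$sup))) {
        best[[v]] <- list(s = s, sup = sel$support[r])
      }
    }
    if (length(best) == 0) {
      expect_equal(nrow(out), 0)
    } else {
      ord <- order(-vapply(best, `[[`, 0, "s"),
                   -vapply(best, `[[`, 0, "sup"), names(best))
      expect_equal(out$value_label, names(best)[ord])
      expect_equal(out$recommendation_score,
                   unname(vapply(best, `[[`, 0, "s"))[ord])
    }
  }
})
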