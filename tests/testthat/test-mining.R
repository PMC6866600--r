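test_that("rule metrics on the example repository match direct counting", {
  repo <- example_instances()
  m <- rule_metrics(repo,
                    antecedent = c(sex = "male", disease = "meningitis"),
                    consequent = c(tissue = "brain"))
  expect_equal(m$support, 2L)
  expect_equal(m$confidence, 1)
  m2 <- rule_metrics(repo, antecedent = c(tissue = "liver"),
                     consequent = c(disease = "liver cancer"))
  expect_equal(m2$support, 2L)
  expect_equal(m2$confidence, 2 / 3)
  # a rule whose pairs appear in every supporting instance has confidence 1
  m3 <- rule_metrics(repo, antecedent = c(disease = "cirrhosis"),
                     consequent = c(tissue = "liver"))
  expect_equal(m3$confidence, 1)
  expect_warning(
    m4 <- rule_metrics(repo, antecedent = c(sex = "unknown"),
                       consequent = c(tissue = "brain")),
    "undefined"
  )
  expect_true(is.na(m4$confidence))
})

test_that("mined rules on the example repository include the documented rules", {
  rules <- mine_rules(example_instances(), min_support = 1,
                      min_confidence = 2 / 3)
  flat <- tidy(rules)
  r1 <- flat[flat$antecedent == "disease=meningitis" &
               flat$consequent_value == "brain", ]
  expect_equal(r1$support, 3L)
  expect_equal(r1$confidence, 1)
  liver <- flat[flat$antecedent == "tissue=liver" &
                  flat$consequent_value == "liver cancer", ]
  expect_equal(liver$support, 2L)
  expect_equal(liver$confidence, 2 / 3, tolerance = 1e-12)
  # ordering: confidence desc, then support desc
  expect_true(all(diff(rules$confidence) <= 1e-12))
})

test_that("a support threshold above the repository size yields no rules", {
  rules <- mine_rules(example_instances(), min_support = 7,
                      min_confidence = 0.5)
  expect_equal(nrow(rules), 0)
  empty <- as_instances(data.frame(template_id = "t", instance_id = "i",
                                   field_label = "sex",
                                   value_label = "male"))[0, ]
  expect_equal(nrow(mine_rules(empty, min_support = 1,
                               min_confidence = 0.5)), 0)
})

test_that("the miner agrees with exhaustive enumeration on random repositories", {
  set.seed(42)
  for (i in 1:30) {
    repo <- random_repository(n_instances = sample(3:8, 1))
    trs <- transactions_of(repo)
    for (thr in list(c(1, 0.5), c(2, 0.3), c(1, 1))) {
      mined <- mine_rules(repo, min_support = thr[1], min_confidence = thr[2])
      expect_same_rules(rules_canonical(mined),
                        oracle_rules(trs, thr[1], thr[2]))
    }
  }
})

test_that("the example repository at min support 1, min confidence 0.5 matches enumeration", {
  repo <- example_instances()
  mined <- mine_rules(repo, min_support = 1, min_confidence = 0.5)
  expect_same_rules(rules_canonical(mined),
                    oracle_rules(transactions_of(repo), 1, 0.5))
})

test_that("the antecedent-size cap is honoured and matches enumeration", {
  set.seed(7)
  repo <- random_repository(n_instances = 8)
  mined <- mine_rules(repo, min_support = 1, min_confidence = 0.3,
                      max_antecedent = 1)
  expect_true(all(lengths(mined$antecedent_keys) <= 1))
  expect_same_rules(rules_canonical(mined),
                    oracle_rules(transactions_of(repo), 1, 0.3,
                                 max_antecedent = 1))
})

test_that("support is anti-monotone and raising thresholds only removes rules", {
  set.seed(99)
  for (i in 1:10) {
    repo <- random_repository()
    lo <- rules_canonical(mine_rules(repo, min_support = 1,
                                     min_confidence = 0.3))
    hi_s <- rules_canonical(mine_rules(repo, min_support = 2,
                                       min_confidence = 0.3))
    hi_c <- rules_canonical(mine_rules(repo, min_support = 1,
                                       min_confidence = 0.7))
    key <- function(df) paste(df$antecedent, df$consequent)
    expect_true(all(key(hi_s) %in% key(lo)))
    expect_true(all(key(hi_c) %in% key(lo)))
    # anti-monotonicity: a rule's joint support never exceeds its antecedent's
    trs <- transactions_of(repo)
    for (r in sample(nrow(lo), min(5, nrow(lo)))) {
      ant <- strsplit(lo$antecedent[r], "|", fixed = TRUE)[[1]]
      n_ant <- sum(vapply(trs, function(t) all(ant %in% t), logical(1)))
      expect_lte(lo$support[r], n_ant)
    }
  }
})

test_that("equivalent URIs collapse to one item and an identical rule set", {
  m <- term_mappings(data.frame(
    a = c("exa:f/tissue", "exa:liver", "exa:brain"),
    b = c("exb:f/tissue", "exb:liver", "exb:brain")
  ))
  mk <- function(ns) as_instances(data.frame(
    template_id = "t",
    instance_id = rep(paste0("i", 1:4), each = 1),
    field_label = "tissue", field_uri = paste0(ns, ":f/tissue"),
    value_label = c("liver", "liver", "brain", "liver"),
    value_uri = paste0(ns, ":", c("liver", "liver", "brain", "liver"))
  ))
  tx_a <- as_transactions(mk("exa"), m, mode = "ontology")
  tx_b <- as_transactions(mk("exb"), m, mode = "ontology")
  expect_equal(sort(unique(tx_a$item)), sort(unique(tx_b$item)))

  # full relabelling of a mined corpus leaves the key-level rule set unchanged
  repo <- example_instances()
  repo$field_uri <- paste0("exa:f/", gsub(" ", "_", repo$field_label))
  repo$value_uri <- paste0("exa:v/", gsub(" ", "_", repo$value_label))
  uris <- unique(c(repo$field_uri, repo$value_uri))
  m2 <- term_mappings(data.frame(a = uris, b = sub("^exa", "exb", uris)))
  relab <- repo
  relab$field_uri <- sub("^exa", "exb", relab$field_uri)
  relab$value_uri <- sub("^exa", "exb", relab$value_uri)
  r_orig <- mine_rules(repo, m2, mode = "ontology", min_support = 1,
                       min_confidence = 0.5)
  r_relab <- mine_rules(relab, m2, mode = "ontology", min_support = 1,
                        min_confidence = 0.5)
  expect_same_rules(rules_canonical(r_orig), rules_canonical(r_relab))
})

test_that("templates are mined separately unless pooling is requested", {
  two <- dplyr::bind_rows(
    example_instances(),
    dplyr::mutate(example_instances(),
                  template_id = "other",
                  instance_id = paste0("J", instance_id))
  )
  separate <- mine_rules(two, min_support = 1, min_confidence = 0.5)
  expect_setequal(unique(separate$template_id), c("experiment", "other"))
  pooled <- mine_rules(two, min_support = 1, min_confidence = 0.5,
                       pool_templates = TRUE)
  expect_equal(unique(pooled$template_id), "pooled")
  # pooling doubles every joint count here, confidences unchanged
  expect_equal(sort(unique(pooled$support)),
               2L * sort(unique(separate$support[
                 separate$template_id == "experiment"])))
})

test_that("rule files round-trip through the JSON schema with mappings", {
  sc <- example_scenarios()$cross_template
  rules <- mine_rules(sc$experiment_instances, mappings = sc$mappings,
                      mode = "ontology", min_support = 1,
                      min_confidence = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_rules(rules, path, mappings = sc$mappings)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_true(all(c("antecedent", "consequent", "support", "confidence",
                    "templateId") %in% names(doc$rules[[1]])))
  expect_true(all(c("fieldLabel", "fieldType", "fieldTypeMappings",
                    "fieldValueLabel", "fieldValueType",
                    "fieldValueMappings") %in% names(doc$rules[[1]]$consequent)))
  back <- read_rules(path)  # equivalences rebuilt from the mappings arrays
  expect_same_rules(rules_canonical(back), rules_canonical(rules))
  # and recommendation through the re-read rules is unchanged
  out <- recommend_values(back, sc$target_field, context = sc$assay_context,
                          mappings = sc$mappings)
  expect_equal(out$value_label[1], "pancreas")
  expect_equal(out$recommendation_score[1], 1)
})
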