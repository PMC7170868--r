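toy_corpus <- data.frame(
  doc_id = c("d1", "d2", "d3"),
  abstract = c("apple apple banana", "banana cherry cherry",
               "banana apple cherry"),
  stringsAsFactors = FALSE)

test_that("preprocessing tokenizes, removes stop words, and keeps uniform counts", {
  prep <- preprocess_abstracts(data.frame(
    doc_id = "d1", abstract = "The apple and the Banana!",
    stringsAsFactors = FALSE))
  expect_setequal(prep$vocabulary, c("apple", "banana"))

  # all three toy tokens have total count 3: the quartile rule removes nothing
  prep <- preprocess_abstracts(toy_corpus)
  expect_equal(prep$vocabulary, c("apple", "banana", "cherry"))
  expect_length(prep$removed_low_frequency, 0)
  expect_equal(unname(prep$counts[1, ]), c(2, 1, 0))
  expect_identical(preprocess_abstracts(toy_corpus)$counts, prep$counts)

  expect_error(preprocess_abstracts(data.frame(doc_id = "d1",
                                               abstract = "the and of")),
               class = "cvt_degenerate_corpus_error")
})

test_that("low-frequency terms strictly below the count quartile are dropped", {
  # counts: common 4x, mid 2x, rare 1x -> q25 of (1,2,4) = 1.5 -> drop "rare"
  corp <- data.frame(
    doc_id = c("a", "b"),
    abstract = c("common common mid rare", "common common mid"),
    stringsAsFactors = FALSE)
  prep <- preprocess_abstracts(corp)
  expect_equal(prep$removed_low_frequency, "rare")
  expect_setequal(prep$vocabulary, c("common", "mid"))
})

test_that("TF-IDF matches a hand computation on the toy corpus", {
  prep <- preprocess_abstracts(toy_corpus)
  w <- tfidf_features(prep)
  # df(apple) = 2, df(banana) = 3, df(cherry) = 2, N = 3
  ia <- log(4 / 3) + 1; ib <- 1
  expect_equal(unname(attr(w, "idf")), c(ia, ib, ia), tolerance = 1e-12)
  d1 <- c(2 * ia, 1 * ib, 0)
  expect_equal(unname(w[1, ]), d1 / sqrt(sum(d1^2)), tolerance = 1e-9)
  d2 <- c(0, 1 * ib, 2 * ia)
  expect_equal(unname(w[2, ]), d2 / sqrt(sum(d2^2)), tolerance = 1e-9)
  d3 <- c(ia, ib, ia)
  expect_equal(unname(w[3, ]), d3 / sqrt(sum(d3^2)), tolerance = 1e-9)
  expect_equal(unname(rowSums(w^2)), c(1, 1, 1), tolerance = 1e-12)

  # featurizing the same abstracts with the stored IDF reproduces the matrix
  w2 <- apply_tfidf(toy_corpus$abstract, prep$vocabulary, attr(w, "idf"))
  expect_equal(unname(w2), unname(w[, , drop = FALSE]), ignore_attr = TRUE)
})

test_that("MeSH enrichment uses a strict sqrt-of-class-size threshold", {
  # 4 positives -> threshold 2: a term needs > 2 documents, i.e. at least 3
  corp <- data.frame(
    label = c(rep("positive", 4), rep("negative", 4)),
    mesh_terms = c("Pharmacokinetics|Rats", "Pharmacokinetics|Rats",
                   "Pharmacokinetics", "Rats|Overlap",
                   "Toxicity|Overlap", "Toxicity|Overlap",
                   "Toxicity|Overlap", "Cells"),
    stringsAsFactors = FALSE)
  fs <- mesh_feature_extraction(corp)
  expect_equal(fs$thresholds, c(positive = 2, negative = 2))
  # Pharmacokinetics: 3 positive docs (> 2, in); Rats: 3 (in);
  # Overlap: 1 positive doc only (out); Cells: 1 negative doc (out)
  expect_setequal(fs$positive_features, c("Pharmacokinetics", "Rats"))
  # Overlap appears in 3 negative docs (> 2) but only on the negative side,
  # so it survives there; Toxicity in 3 (> 2)
  expect_setequal(fs$negative_features, c("Overlap", "Toxicity"))
})

test_that("MeSH features qualifying in both classes are removed from both", {
  corp <- data.frame(
    label = c(rep("positive", 4), rep("negative", 4)),
    mesh_terms = c(rep("Both|PosOnly", 3), "Both",
                   rep("Both|NegOnly", 3), "Both"),
    stringsAsFactors = FALSE)
  fs <- mesh_feature_extraction(corp)
  expect_false("Both" %in% fs$positive_features)
  expect_false("Both" %in% fs$negative_features)
  expect_equal(fs$positive_features, "PosOnly")
  expect_equal(fs$negative_features, "NegOnly")
})

test_that("the MeSH rule is: any positive feature and no negative feature", {
  fs <- structure(list(positive_features = c("P1", "P2"),
                       negative_features = "N1",
                       thresholds = c(positive = 1, negative = 1)),
                  class = "mesh_feature_sets")
  expect_equal(mesh_rule_classify(c("P1"), fs), "positive")
  expect_equal(mesh_rule_classify(c("P1", "N1"), fs), "negative")
  expect_equal(mesh_rule_classify(c("Other"), fs), "negative")
  expect_equal(mesh_rule_classify(character(0), fs), "negative")
  df <- data.frame(mesh_terms = c("P1|P2", "P2|N1", ""),
                   stringsAsFactors = FALSE)
  expect_equal(mesh_rule_classify(df, fs),
               c("positive", "negative", "negative"))
})

test_that("a separable corpus retains every member family", {
  corp <- simulate_abstract_corpus(corpus_design(seed = 31))
  ens <- train_consensus_ensemble(corp, ensemble_spec(random_seed = 2))
  expect_setequal(ens$retained, names(ensemble_member_families()))
  expect_true(all(ens$cv_accuracies >= 0.9))
})

test_that("an uninformative corpus yields an empty-ensemble error", {
  corp <- simulate_abstract_corpus(corpus_design(separation = 0, seed = 32))
  expect_error(train_consensus_ensemble(corp, ensemble_spec(random_seed = 2)),
               class = "cvt_empty_ensemble_error")
})

test_that("training and classification are deterministic and seed-isolated", {
  corp <- simulate_abstract_corpus(corpus_design(seed = 33))
  newdocs <- simulate_abstract_corpus(corpus_design(n_positive = 10,
                                                    n_negative = 10,
                                                    seed = 34))
  set.seed(1234); before <- .Random.seed
  e1 <- train_consensus_ensemble(corp, ensemble_spec(random_seed = 5))
  p1 <- consensus_classify(e1, newdocs)
  expect_identical(.Random.seed, before)   # global RNG stream untouched
  e2 <- train_consensus_ensemble(corp, ensemble_spec(random_seed = 5))
  p2 <- consensus_classify(e2, newdocs)
  expect_identical(e1$cv_accuracies, e2$cv_accuracies)
  expect_identical(e1$retained, e2$retained)
  expect_identical(p1, p2)
})

test_that("unanimity positives are a subset of 75%-consensus positives", {
  corp <- simulate_abstract_corpus(corpus_design(separation = 0.6,
                                                 seed = 35))
  holdout <- simulate_abstract_corpus(corpus_design(n_positive = 15,
                                                    n_negative = 15,
                                                    separation = 0.6,
                                                    seed = 36))
  ens <- train_consensus_ensemble(
    corp, ensemble_spec(accuracy_inclusion_threshold = 0.6, random_seed = 3))
  strict <- consensus_classify(ens, holdout, consensus_fraction = 1)
  lax <- consensus_classify(ens, holdout, consensus_fraction = 0.75)
  expect_true(all(which(strict == "positive") %in%
                    which(lax == "positive")))
})

test_that("the full pipeline classifies a held-out separable corpus accurately", {
  corp <- simulate_abstract_corpus(corpus_design(seed = 41))
  holdout <- simulate_abstract_corpus(corpus_design(n_positive = 20,
                                                    n_negative = 20,
                                                    seed = 42))
  ens <- train_consensus_ensemble(corp, ensemble_spec(random_seed = 7))
  pred <- consensus_classify(ens, holdout, consensus_fraction = 0.75)
  acc <- mean(pred == holdout$label)
  expect_gte(acc, 0.95)

  # the MeSH rule also separates the synthetic pools
  fs <- mesh_feature_extraction(corp)
  mpred <- mesh_rule_classify(holdout, fs)
  expect_gte(mean(mpred == holdout$label), 0.9)
})
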