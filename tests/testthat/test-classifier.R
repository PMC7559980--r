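# shared small training setup: separable corpus, low-dimensional embeddings
make_clf_fixture <- function(n = 300, dim = 24, seed = 5) {
  cfg <- generator_config(n_records = n, violence_prevalence = 0.1, seed = seed)
  corp <- generate_corpus(cfg)
  cleaned <- clean_text(corp$text, cfg$dictionary)$text
  toks <- lapply(cleaned, function(t) as.character(tokenize(t)))
  emb <- train_embeddings(toks, dimension = dim, min_count = 1, epochs = 2,
                          seed = seed)
  list(corp = corp, cleaned = cleaned, emb = emb,
       vocab = build_vocab_map(cleaned))
}

test_that("the layer stack matches the published architecture", {
  fx <- make_clf_fixture(n = 80)
  cfg <- classifier_config(embedding_dim = 24, max_sequence_length = 30,
                           seed = 1)
  m <- build_model(fx$vocab, fx$emb, cfg)
  types <- vapply(m$layers, `[[`, "", "type")
  expect_identical(types, c("embedding", "dropout", "conv1d",
                            "max_pooling1d", "lstm", "dense"))
  expect_identical(m$layers[[2]]$rate, 0.2)
  expect_identical(m$layers[[3]]$filters, 64)
  expect_identical(m$layers[[3]]$kernel_size, 5)
  expect_identical(m$layers[[3]]$activation, "relu")
  expect_identical(m$layers[[4]]$pool_size, 4)
  expect_identical(m$layers[[5]]$units, 100)
  expect_identical(m$layers[[6]]$activation, "sigmoid")
  # conv kernel shape follows from the stated sizes: (K*D) x F
  expect_identical(dim(m$params$Wc), c(5L * 24L, 64L))
  # defaults reproduce the published constants
  dflt <- classifier_config()
  expect_identical(c(dflt$embedding_dim, dflt$conv_filters, dflt$kernel_size,
                     dflt$pool_size, dflt$lstm_units),
                   c(300, 64, 5, 4, 100))
  expect_identical(dflt$dropout_rate, 0.2)
})

test_that("configuration errors are caught", {
  fx <- make_clf_fixture(n = 80)
  expect_error(build_model(fx$vocab, fx$emb,
                           classifier_config(embedding_dim = 300)),
               "dimension mismatch")
  expect_error(classifier_config(dropout_rate = 1), "dropout")
  expect_error(classifier_config(conv_filters = 0), "positive")
})

test_that("training is reproducible and stratifies the validation split", {
  fx <- make_clf_fixture(n = 240)
  cfg <- classifier_config(embedding_dim = 24, max_sequence_length = 30,
                           epochs = 2, seed = 11)
  m1 <- train_classifier(build_model(fx$vocab, fx$emb, cfg),
                         fx$cleaned, fx$corp$label)
  m2 <- train_classifier(build_model(fx$vocab, fx$emb, cfg),
                         fx$cleaned, fx$corp$label)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # stratification: validation prevalence within one record of the corpus rate
  n_val <- round(240 * cfg$validation_split)
  expect_lte(abs(m1$val_prevalence * n_val - 0.1 * n_val), 1)
  # single-class input is a data error
  expect_error(train_classifier(build_model(fx$vocab, fx$emb, cfg),
                                fx$cleaned[fx$corp$label == "NV"],
                                rep("NV", sum(fx$corp$label == "NV"))),
               "both classes")
})

test_that("prediction is deterministic and total on degenerate input", {
  fx <- make_clf_fixture(n = 240)
  cfg <- classifier_config(embedding_dim = 24, max_sequence_length = 30,
                           epochs = 3, seed = 11)
  m <- train_classifier(build_model(fx$vocab, fx$emb, cfg),
                        fx$cleaned, fx$corp$label)
  p1 <- predict_label(m, fx$cleaned[1:10])
  p2 <- predict_label(m, fx$cleaned[1:10])
  expect_identical(p1, p2)
  expect_true(all(p1$probability >= 0 & p1$probability <= 1))
  expect_identical(p1$label, ifelse(p1$probability >= 0.5, "V", "NV"))
  # empty text yields the all-padding prediction, no crash
  p0 <- predict_label(m, "")
  expect_identical(nrow(p0), 1L)
  expect_false(is.na(p0$probability))
  # untrained model refuses to predict
  expect_error(predict_label(build_model(fx$vocab, fx$emb, cfg), "x"),
               "trained")
})

test_that("a separable corpus is learned to high validation F1", {
  fx <- make_clf_fixture(n = 400, dim = 24, seed = 9)
  cfg <- classifier_config(embedding_dim = 24, max_sequence_length = 30,
                           epochs = 10, patience = 3, seed = 2)
  m <- train_classifier(build_model(fx$vocab, fx$emb, cfg),
                        fx$cleaned, fx$corp$label)
  expect_gte(max(m$history$val_f1_v), 0.9)
  preds <- predict_label(m, fx$cleaned, ids = fx$corp$id)
  rep_ <- classification_metrics(preds, fx$corp[, c("id", "label")])
  expect_gte(rep_$per_class["V", "f1"], 0.9)
})
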