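test_that("classification metrics reproduce hand-checked confusion tables", {
  ids <- as.character(1:4)
  all_right <- data.frame(id = ids, label = c("V", "V", "NV", "NV"))
  rep0 <- classification_metrics(all_right, all_right)
  expect_equal(unlist(rep0$per_class), rep(1, 6), ignore_attr = TRUE)
  # the published worked example: TP=2073, predicted-positive=2291,
  # actual-positive=2584 in a 76,911-record test half
  n <- 76911
  tp <- 2073; pred_pos <- 2291; act_pos <- 2584
  gold <- rep("NV", n); gold[1:act_pos] <- "V"
  pred <- rep("NV", n)
  pred[1:tp] <- "V"                                   # true positives
  pred[(act_pos + 1):(act_pos + pred_pos - tp)] <- "V" # false positives
  rep1 <- classification_metrics(data.frame(id = 1:n, label = pred),
                                 data.frame(id = 1:n, label = gold))
  expect_equal(rep1$per_class["V", "precision"], 0.905, tolerance = 5e-4)
  expect_equal(rep1$per_class["V", "recall"], 0.802, tolerance = 5e-4)
  expect_equal(unname(rep1$counts["tp"]), tp)
  # id mismatch is a data error
  expect_error(classification_metrics(all_right[1:3, ], all_right), "id")
})

test_that("ranked-retrieval metrics match worked examples", {
  # single gold item ranked first
  expect_equal(map_score(list(c("a", "b")), list("a")), 1.0)
  # gold at ranks 1 and 3 of a 3-item ranking
  expect_equal(map_score(list(c("a", "x", "b")), list(c("a", "b"))),
               (1 + 2 / 3) / 2, tolerance = 1e-6)
  # gold absent from the ranking
  expect_equal(map_score(list(c("x", "y")), list("a")), 0)
  # S@k contributions
  expect_equal(success_at_k(list(c("a", "b")), list("a"), 1), 1)
  expect_equal(success_at_k(list(c("x", "y", "z", "w", "a")), list("a"), 1), 0)
  expect_equal(success_at_k(list(c("x", "y", "z", "w", "a")), list("a"), 5), 1)
  # R@5
  expect_equal(recall_at_k(list(c("a", "b", "x", "y", "z")), list(c("a", "b"))), 1)
  expect_equal(recall_at_k(list(c("a", "x", "y", "z", "w")), list(c("a", "b"))), 0.5)
})

test_that("metrics agree with brute-force oracles on randomized cases", {
  set.seed(17)
  universe <- paste0("w", 1:12)
  for (trial in 1:100) {
    n_cases <- sample(1:6, 1)
    rankings <- replicate(n_cases, sample(universe, sample(1:8, 1)),
                          simplify = FALSE)
    gold <- replicate(n_cases, sample(universe, sample(1:3, 1)),
                      simplify = FALSE)
    k <- sample(1:5, 1)
    expect_equal(map_score(rankings, gold),
                 mean(mapply(oracle_ap, rankings, gold)))
    expect_equal(success_at_k(rankings, gold, k),
                 mean(mapply(oracle_s_at_k, rankings, gold, k)))
    expect_equal(recall_at_k(rankings, gold, k),
                 mean(mapply(oracle_r_at_k, rankings, gold, k)))
  }
  # P/R/F1 against the counting oracle on random 20-item tables
  for (trial in 1:30) {
    pred <- sample(c("V", "NV"), 20, replace = TRUE)
    gold <- sample(c("V", "NV"), 20, replace = TRUE)
    rp <- classification_metrics(data.frame(id = 1:20, label = pred),
                                 data.frame(id = 1:20, label = gold))
    ov <- oracle_prf(pred, gold, "V")
    on_ <- oracle_prf(pred, gold, "NV")
    expect_equal(unlist(rp$per_class["V", ]), ov, ignore_attr = TRUE)
    expect_equal(unlist(rp$per_class["NV", ]), on_, ignore_attr = TRUE)
  }
})

test_that("empty-gold cases are excluded and S@1 <= S@5 always holds", {
  rankings <- list(c("a", "b"), c("c", "d"), c("e"))
  gold <- list("b", character(0), "e")   # middle case excluded
  expect_equal(success_at_k(rankings, gold, 1), 0.5)
  expect_equal(map_score(rankings, gold), (0.5 + 1) / 2)
  set.seed(23)
  for (trial in 1:25) {
    rk <- replicate(4, sample(letters, 6), simplify = FALSE)
    gd <- replicate(4, sample(letters, 2), simplify = FALSE)
    expect_lte(success_at_k(rk, gd, 1), success_at_k(rk, gd, 5))
    expect_lte(recall_at_k(rk, gd, 5), 1)
  }
  # singleton gold returned at rank 1 for every case: MAP = S@1 = R@5 = 1
  rk1 <- list(c("a", "x"), c("b", "y"))
  gd1 <- list("a", "b")
  expect_equal(map_score(rk1, gd1), success_at_k(rk1, gd1, 1))
  expect_equal(map_score(rk1, gd1), recall_at_k(rk1, gd1, 5))
})
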