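lex <- read_lexicon()
schema <- default_frame_schema()

test_that("candidate generation collapses duplicates, identically per field", {
  expect_length(generate_candidates(tokenize("")), 0L)
  cand <- generate_candidates(token_sequence(c("fist", "fist", "trauma")))
  expect_identical(as.character(cand), c("fist", "trauma"))
  seq <- mark_extended_tokens(tokenize("known person hit her with a punch"),
                              "known person")
  expect_setequal(as.character(generate_candidates(seq)),
                  unique(as.character(seq)))
})

test_that("PoS/SST pruning applies the compatibility sets with the bypass", {
  agent <- schema$fields$AGENT
  body <- schema$fields$BODY_PART
  cand <- token_sequence(c("husband", "arm", "qqzz"))
  expect_identical(as.character(prune_candidates(cand, agent, lex)), "husband")
  expect_identical(as.character(prune_candidates(cand, body, lex)), "arm")
  # extended tokens bypass both filters everywhere
  cand2 <- token_sequence(c("husband", "known_person"), c(FALSE, TRUE))
  expect_identical(as.character(prune_candidates(cand2, body, lex)),
                   "known_person")
  expect_setequal(as.character(prune_candidates(cand2, agent, lex)),
                  c("husband", "known_person"))
  # LESION_TYPE admits adjectives via adj.all
  lesion <- schema$fields$LESION_TYPE
  expect_setequal(as.character(prune_candidates(
    token_sequence(c("swollen", "fracture", "home")), lesion, lex)),
    c("swollen", "fracture"))
})

test_that("ranking orders by cosine with lexicographic tie-break", {
  emb <- make_embeddings(rbind(p = c(1, 0), a = c(1, 1), b = c(0, 1),
                               c = c(1, 0.2)))
  pr <- build_prototype(field_spec("AGENT", "NOUN", "noun.person", "p"), emb)
  rk <- rank_candidates(token_sequence(c("a", "b", "c")), pr, emb)
  # hand-computed cosines to (1,0): c = .981, a = .707, b = 0
  expect_identical(rk$token, c("c", "a", "b"))
  expect_equal(rk$score, c(1 / sqrt(1.04), 1 / sqrt(2), 0), tolerance = 1e-6)
  # candidate equal to the prototype ranks first with score 1
  rk2 <- rank_candidates(token_sequence(c("a", "p")), pr, emb)
  expect_identical(rk2$token[1], "p")
  expect_equal(rk2$score[1], 1.0)
  # unrankable (no-vector) tokens are dropped and reported
  rk3 <- rank_candidates(token_sequence(c("a", "zz")), pr, emb)
  expect_identical(rk3$token, "a")
  expect_identical(attr(rk3, "dropped"), "zz")
  # empty candidate set gives an empty ranking
  expect_identical(nrow(rank_candidates(token_sequence(character(0)), pr, emb)), 0L)
})

test_that("threshold and closest-field rules match exhaustive enumeration", {
  mk <- function(tokens, scores) {
    structure(data.frame(token = tokens[order(-scores, tokens)],
                         score = sort(scores, decreasing = TRUE),
                         stringsAsFactors = FALSE),
              class = c("vf_ranking", "data.frame"))
  }
  # the documented two-field case: kept only where the score is higher
  rks <- list(AGENT = mk("x", 0.7), MODE_INSTRUMENT = mk("x", 0.6))
  fr <- resolve_assignments(rks, 0.5)
  expect_identical(fr$AGENT$token, "x")
  expect_identical(nrow(fr$MODE_INSTRUMENT), 0L)
  # all below threshold: empty frame
  fr2 <- resolve_assignments(list(A = mk("x", 0.2), B = mk("y", 0.4)), 0.5)
  expect_true(all(vapply(fr2, nrow, 0L) == 0L))
  # randomized trials vs the enumeration oracle
  set.seed(99)
  for (trial in 1:120) {
    n_tok <- sample(2:8, 1)
    toks <- paste0("t", seq_len(n_tok))
    n_f <- sample(2:4, 1)
    fields <- LETTERS[seq_len(n_f)]
    rks <- lapply(fields, function(f) {
      keep <- runif(n_tok) < 0.8
      mk(toks[keep], round(runif(sum(keep)), 3))
    })
    names(rks) <- fields
    thr <- 0.3
    got <- resolve_assignments(rks, thr)
    want <- oracle_assign(rks, thr)
    for (f in fields) expect_identical(sort(got[[f]]$token), want[[f]])
  }
})

test_that("a token never fills two fields and thresholds are monotone", {
  lexf <- read_lexicon()
  corpus <- c(
    "tonight husband punched her at home causing a fracture on the arm",
    "yesterday evening stranger attacked wife with knife at school wound face")
  toks <- lapply(corpus, function(t) as.character(tokenize(t)))
  emb <- train_embeddings(c(toks, toks, toks, toks), dimension = 12,
                          min_count = 1, epochs = 3, seed = 5)
  prev_total <- Inf
  for (thr in c(0.1, 0.4, 0.7, 0.95)) {
    sch <- default_frame_schema(similarity_threshold = thr)
    fr <- extract_frame(corpus[1], sch, emb, lexf)
    fillers <- unlist(lapply(fr, function(df) df$token))
    expect_identical(anyDuplicated(fillers), 0L)
    total <- length(fillers)
    expect_lte(total, prev_total)
    prev_total <- total
  }
})

test_that("frame extraction recovers a hand-checkable planted sentence", {
  # embeddings crafted so each gold filler is nearest its own prototype
  base <- diag(6)
  vecs <- rbind(
    tonight = base[1, ] + 0.05, husband = base[2, ] + 0.05,
    punch = base[3, ] + 0.05, home = base[4, ] + 0.05,
    arm = base[5, ] + 0.05, fracture = base[6, ] + 0.05,
    evening = base[1, ], known_person = base[2, ], knife = base[3, ],
    workplace = base[4, ], head = base[5, ], contusion = base[6, ],
    night = base[1, ], trauma = base[6, ],
    causing = rep(0.1, 6), the = rep(0.1, 6), a = rep(0.1, 6),
    at = rep(0.1, 6), on = rep(0.1, 6), her = rep(0.1, 6)
  )
  emb <- make_embeddings(vecs)
  lexf <- read_lexicon()
  # "tonight" is not in the fixture lexicon; add it as a time noun
  lexf <- lexicon(c(lexf$entries$lemma, "tonight"),
                  c(lexf$entries$pos, "NOUN"),
                  c(vapply(lexf$groups, function(g)
                      paste(vapply(g, paste, "", collapse = ","), collapse = ";"), ""),
                    "noun.time"))
  txt <- "tonight husband punched her at home causing a fracture on the arm"
  fr <- extract_frame(txt, default_frame_schema(), emb, lexf)
  expect_identical(fr$TIME$token, "tonight")
  expect_identical(fr$AGENT$token, "husband")
  expect_identical(fr$LOCATION$token, "home")
  expect_identical(fr$BODY_PART$token, "arm")
  expect_identical(fr$LESION_TYPE$token, "fracture")
  # empty record: all-empty frame
  fr0 <- extract_frame("", default_frame_schema(), emb, lexf)
  expect_true(all(vapply(fr0, nrow, 0L) == 0L))
})

test_that("disabling filters never shrinks the pre-threshold rankings", {
  lexf <- read_lexicon()
  txt <- "husband attacked wife with knife at home causing wound of the arm"
  seed_cover <- c(
    "in the evening or night a punch at home or the workplace",
    "husband or known person hit arm and head",
    "fracture contusion trauma after a knife")
  toks <- lapply(c(txt, seed_cover), function(t)
    as.character(mark_extended_tokens(tokenize(t), "known person")))
  emb <- train_embeddings(rep(toks, 15), dimension = 10, min_count = 1,
                          epochs = 3, seed = 8)
  fr_on <- extract_frame(txt, schema, emb, lexf, use_filters = TRUE)
  fr_off <- extract_frame(txt, schema, emb, lexf, use_filters = FALSE)
  for (f in FRAME_FIELDS) {
    expect_true(all(attr(fr_on, "rankings")[[f]]$token %in%
                    attr(fr_off, "rankings")[[f]]$token))
  }
})

test_that("schema files reproduce the built-in compatibility table", {
  sch <- read_frame_schema(system.file("extdata", "frame_schema.yaml",
                                       package = "violframe"))
  expect_identical(names(sch$fields), FRAME_FIELDS)
  expect_equal(sch$similarity_threshold, 0.5)
  for (f in FRAME_FIELDS) {
    expect_setequal(sch$fields[[f]]$allowed_pos, schema$fields[[f]]$allowed_pos)
    expect_setequal(sch$fields[[f]]$allowed_sst, schema$fields[[f]]$allowed_sst)
  }
  expect_error(frame_schema(list(schema$fields$AGENT), similarity_threshold = 0),
               "threshold")
})
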