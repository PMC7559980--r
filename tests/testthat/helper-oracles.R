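# Independent brute-force oracles used to cross-check the package's
# metric and assignment implementations. Deliberately written as plain
# loops over definitions, never calling the functions they check.

oracle_prf <- function(pred_labels, gold_labels, positive) {
  tp <- fp <- fn <- 0
  for (i in seq_along(pred_labels)) {
    if (pred_labels[i] == positive && gold_labels[i] == positive) tp <- tp + 1
    if (pred_labels[i] == positive && gold_labels[i] != positive) fp <- fp + 1
    if (pred_labels[i] != positive && gold_labels[i] == positive) fn <- fn + 1
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(p = p, r = r, f = f)
}

oracle_ap <- function(ranking, gold) {
  gold <- unique(gold)
  if (length(gold) == 0) return(NA_real_)
  hits <- 0
  s <- 0
  for (i in seq_along(ranking)) {
    if (ranking[i] %in% gold) {
      hits <- hits + 1
      s <- s + hits / i
    }
  }
  s / length(gold)
}

oracle_s_at_k <- function(ranking, gold, k) {
  top <- ranking[seq_len(min(k, length(ranking)))]
  as.numeric(length(intersect(top, gold)) > 0)
}

oracle_r_at_k <- function(ranking, gold, k) {
  gold <- unique(gold)
  top <- ranking[seq_len(min(k, length(ranking)))]
  length(intersect(top, gold)) / length(gold)
}

# Exhaustive-enumeration oracle for threshold + closest-field assignment.
# Enumerates every token -> (field or none) map in which a token may only
# go to a field where it scores at or above the threshold, and returns the
# map with maximal total score (unique with continuous random scores).
oracle_assign <- function(rankings, threshold) {
  fields <- names(rankings)
  toks <- unique(unlist(lapply(rankings, function(r) r$token)))
  score_of <- function(tok, f) {
    i <- match(tok, rankings[[f]]$token)
    if (is.na(i)) NA_real_ else rankings[[f]]$score[i]
  }
  opts <- lapply(toks, function(tk) {
    el <- fields[vapply(fields, function(f) {
      s <- score_of(tk, f); !is.na(s) && s >= threshold
    }, logical(1))]
    c(el, NA_character_)
  })
  best_total <- -Inf
  best <- NULL
  grid <- expand.grid(lapply(opts, seq_along))
  for (g in seq_len(nrow(grid))) {
    assign_ <- vapply(seq_along(toks), function(j) opts[[j]][grid[g, j]], "")
    total <- 0
    for (j in seq_along(toks)) {
      if (!is.na(assign_[j])) total <- total + score_of(toks[j], assign_[j])
    }
    if (total > best_total) {
      best_total <- total
      best <- assign_
    }
  }
  out <- lapply(fields, function(f) sort(toks[!is.na(best) & best == f]))
  names(out) <- fields
  out
}

# hand-set embedding model for deterministic ranking tests
make_embeddings <- function(vectors) {
  vocab <- seq_len(nrow(vectors))
  names(vocab) <- rownames(vectors)
  structure(list(dim = ncol(vectors), vocab = vocab, vectors = vectors),
            class = "vf_embeddings")
}
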