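#' Train skip-gram word embeddings on a tokenized corpus
#'
#' Skip-gram with negative sampling (SGNS), trained directly on the cleaned
#' corpus so that the vector space reflects the narratives' own usage
#' (including extended tokens such as `known_person`, which receive vectors
#' like any other token). The implementation is vectorized base R: training
#' pairs are drawn from a fixed symmetric context window, shuffled once per
#' epoch, and processed in mini-batches whose gradients are aggregated with
#' `rowsum()`, which makes the whole run reproducible under a single seed.
#' Negative contexts are sampled from the unigram distribution raised to
#' 3/4. The learning rate decays linearly over the run.
#'
#' @param corpus list of token sequences (character vectors or `vf_tokens`).
#' @param dimension embedding dimensionality (default 300).
#' @param window symmetric context window size (default 5).
#' @param min_count minimum token frequency to enter the vocabulary
#'   (default 2; rarer tokens get no vector and report as out-of-vocabulary).
#' @param negative number of negative samples per positive pair (default 5).
#' @param epochs passes over the pair set (default 10).
#' @param learning_rate initial SGD step size (default 0.05).
#' @param batch_size pairs per aggregated update (default 4096).
#' @param vectors which vectors to expose: `"average"` (the mean of input
#'   and output matrices, the usual choice on small corpora, where it also
#'   captures first-order co-occurrence) or `"input"` (word2vec's classic
#'   convention).
#' @param seed integer seed controlling initialization, shuffling and
#'   negative sampling.
#' @return A `vf_embeddings` object: fields `dim`, `vocab` (named index) and
#'   `vectors` (matrix, one row per token).
#' @export
train_embeddings <- function(corpus, dimension = 300, window = 5, min_count = 2,
                             negative = 5, epochs = 10, learning_rate = 0.05,
                             batch_size = 4096, vectors = c("average", "input"),
                             seed = 1L) {
  vectors <- match.arg(vectors)
  corpus <- lapply(corpus, as.character)
  corpus <- corpus[lengths(corpus) > 0L]
  if (length(corpus) == 0L) stop("empty corpus: nothing to train on")
  stopifnot(dimension >= 1, window >= 1, negative >= 0, epochs >= 1)

  counts <- table(unlist(corpus))
  vocab_tokens <- names(counts)[counts >= min_count]
  if (length(vocab_tokens) < 2L) {
    stop("vocabulary too small after min_count filtering")
  }
  vocab_tokens <- sort(vocab_tokens)
  V <- length(vocab_tokens)
  vocab <- seq_len(V)
  names(vocab) <- vocab_tokens

  # all (center, context) pairs within the fixed window, OOV dropped
  sent_ids <- lapply(corpus, function(s) unname(vocab[s[s %in% vocab_tokens]]))
  sent_ids <- sent_ids[lengths(sent_ids) >= 2L]
  if (length(sent_ids) == 0L) stop("no sentence with two in-vocabulary tokens")
  pair_list <- lapply(sent_ids, function(ids) {
    n <- length(ids)
    off <- seq_len(window)
    ctr <- ctx <- integer(0)
    for (d in off) {
      if (n > d) {
        i <- seq_len(n - d)
        ctr <- c(ctr, ids[i], ids[i + d])
        ctx <- c(ctx, ids[i + d], ids[i])
      }
    }
    cbind(ctr, ctx)
  })
  pairs <- do.call(rbind, pair_list)
  n_pairs <- nrow(pairs)

  freq <- as.numeric(counts[vocab_tokens])
  neg_prob <- freq^0.75
  neg_prob <- neg_prob / sum(neg_prob)

  set.seed(seed)
  W_in <- matrix(stats::runif(V * dimension, -0.5, 0.5) / dimension, nrow = V)
  W_out <- matrix(0, nrow = V, ncol = dimension)

  total_steps <- epochs * ceiling(n_pairs / batch_size)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_pairs)
    for (start in seq(1L, n_pairs, by = batch_size)) {
      step <- step + 1L
      lr <- learning_rate * max(1 - (step - 1L) / total_steps, 1e-4)
      sel <- ord[start:min(start + batch_size - 1L, n_pairs)]
      b <- length(sel)
      ctr <- pairs[sel, 1L]
      pos <- pairs[sel, 2L]
      negs <- sample.int(V, b * negative, replace = TRUE, prob = neg_prob)
      ctx_idx <- c(pos, negs)
      rep_ctr <- rep.int(ctr, 1L + negative)
      lab <- rep(c(1, 0), times = c(b, b * negative))
      Vc <- W_in[rep_ctr, , drop = FALSE]
      U <- W_out[ctx_idx, , drop = FALSE]
      g <- 1 / (1 + exp(-rowSums(Vc * U))) - lab   # d loss / d score
      # group-mean updates keep aggregated steps bounded for frequent tokens
      upd_in <- rowsum(g * U, group = rep_ctr)
      cnt_in <- rowsum(rep(1, length(rep_ctr)), group = rep_ctr)
      ri <- as.integer(rownames(upd_in))
      W_in[ri, ] <- W_in[ri, , drop = FALSE] - lr * upd_in / as.vector(cnt_in)
      upd_out <- rowsum(g * Vc, group = ctx_idx)
      cnt_out <- rowsum(rep(1, length(ctx_idx)), group = ctx_idx)
      ro <- as.integer(rownames(upd_out))
      W_out[ro, ] <- W_out[ro, , drop = FALSE] - lr * upd_out / as.vector(cnt_out)
    }
  }
  W <- switch(vectors,
              average = (W_in + W_out) / 2,
              input = W_in,
              stop("vectors must be 'average' or 'input'"))
  rownames(W) <- vocab_tokens
  structure(list(dim = as.integer(dimension), vocab = vocab, vectors = W),
            class = "vf_embeddings")
}

#' @export
print.vf_embeddings <- function(x, ...) {
  cat("<vf_embeddings> ", length(x$vocab), " tokens, ", x$dim, "-d\n", sep = "")
  invisible(x)
}

#' Look up embedding vectors
#'
#' @param model a `vf_embeddings`.
#' @param token a single token.
#' @return The token's vector, or `NULL` if out of vocabulary.
#' @export
embedding_vector <- function(model, token) {
  i <- unname(model$vocab[token])
  if (is.na(i)) return(NULL)
  model$vectors[i, ]
}

#' @rdname embedding_vector
#' @export
in_vocabulary <- function(model, token) !is.na(unname(model$vocab[token]))

#' Cosine similarity between two vectors
#'
#' @param u,v numeric vectors of equal length, neither all-zero.
#' @return Cosine similarity in `[-1, 1]`; symmetric in its arguments.
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Build a field prototype vector from seed terms
#'
#' The prototype is the arithmetic mean of the embedding vectors of the
#' field's seed terms - a synthetic description of the semantic role (e.g.
#' the mean of "husband" and "known_person" for the agent slot), against
#' which record tokens are ranked by cosine similarity. Seeds absent from
#' the vocabulary are skipped and reported; duplicated seeds are kept, so
#' repetition acts as frequency weighting. If no seed is in vocabulary a
#' configuration error is signalled.
#'
#' @param field_spec a `vf_field_spec` (see [field_spec()]), or any list
#'   with `name` and `seed_terms`.
#' @param model a `vf_embeddings`.
#' @return A `vf_prototype`: list with `field`, `seed_terms`, `vector`,
#'   `missing_seeds`.
#' @export
build_prototype <- function(field_spec, model) {
  seeds <- field_spec$seed_terms
  if (length(seeds) == 0L) stop("field ", field_spec$name, ": empty seed-term list")
  present <- vapply(seeds, function(s) in_vocabulary(model, s), logical(1))
  if (!any(present)) {
    stop("field ", field_spec$name, ": no seed term in embedding vocabulary")
  }
  mat <- model$vectors[unname(model$vocab[seeds[present]]), , drop = FALSE]
  structure(list(
    field = field_spec$name,
    seed_terms = seeds,
    vector = colMeans(mat),
    missing_seeds = seeds[!present]
  ), class = "vf_prototype")
}

#' Write embeddings in word2vec text format
#'
#' Header line `vocab_size dimension`, then one line per token:
#' the token followed by its vector components, space-separated.
#'
#' @param model a `vf_embeddings`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(length(model$vocab), model$dim), con)
  toks <- names(model$vocab)
  for (i in seq_along(toks)) {
    writeLines(paste(toks[i], paste(format(model$vectors[i, ], scientific = FALSE,
                                           trim = TRUE, digits = 8),
                                    collapse = " ")), con)
  }
  invisible(path)
}

#' Read embeddings from word2vec text format
#'
#' @param path file written by [write_embeddings()] or any tool using the
#'   word2vec text convention.
#' @return A `vf_embeddings`.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]])
  n <- hdr[1L]; d <- hdr[2L]
  parts <- strsplit(trimws(lines[1L + seq_len(n)]), "[[:space:]]+")
  toks <- vapply(parts, `[[`, "", 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(d)))
  rownames(vecs) <- toks
  vocab <- seq_len(n); names(vocab) <- toks
  structure(list(dim = d, vocab = vocab, vectors = vecs), class = "vf_embeddings")
}
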