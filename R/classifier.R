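#' Classifier configuration
#'
#' Hyperparameters of the convolutional-recurrent categorizer. The
#' architecture constants (300-d embeddings, 64 convolution filters of
#' kernel size 5, 20% dropout between embedding and convolution, max
#' pooling of window 4, a 100-unit LSTM, one sigmoid output unit) are the
#' published design; sequence length, batch size, epoch budget and the
#' Adam step size are conventional defaults and freely configurable.
#'
#' @param embedding_dim embedding dimensionality (default 300).
#' @param conv_filters number of 1-D convolution filters (default 64).
#' @param kernel_size convolution kernel width in tokens (default 5).
#' @param dropout_rate dropout between embedding and convolution
#'   (default 0.2, in `[0, 1)`).
#' @param pool_size max-pooling window (default 4).
#' @param lstm_units LSTM memory units (default 100).
#' @param max_sequence_length pad/truncate length in tokens (default 100).
#' @param batch_size minibatch size (default 32).
#' @param epochs maximum training epochs (default 10).
#' @param learning_rate Adam step size (default 0.001).
#' @param patience early-stopping patience on validation loss (default 2).
#' @param validation_split held-out fraction, class-stratified
#'   (default 0.2).
#' @param threshold decision threshold on the sigmoid output (default 0.5).
#' @param class_weight optional named vector `c(V = , NV = )` of loss
#'   weights; `NULL` (the default) applies none.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return A `vf_classifier_config` list.
#' @export
classifier_config <- function(embedding_dim = 300, conv_filters = 64,
                              kernel_size = 5, dropout_rate = 0.2,
                              pool_size = 4, lstm_units = 100,
                              max_sequence_length = 100, batch_size = 32,
                              epochs = 10, learning_rate = 0.001,
                              patience = 2, validation_split = 0.2,
                              threshold = 0.5, class_weight = NULL,
                              seed = 1L) {
  cfg <- list(embedding_dim = embedding_dim, conv_filters = conv_filters,
              kernel_size = kernel_size, dropout_rate = dropout_rate,
              pool_size = pool_size, lstm_units = lstm_units,
              max_sequence_length = max_sequence_length,
              batch_size = batch_size, epochs = epochs,
              learning_rate = learning_rate, patience = patience,
              validation_split = validation_split, threshold = threshold,
              class_weight = class_weight, seed = as.integer(seed))
  counts <- c(cfg$embedding_dim, cfg$conv_filters, cfg$kernel_size,
              cfg$pool_size, cfg$lstm_units, cfg$max_sequence_length,
              cfg$batch_size, cfg$epochs)
  if (any(counts < 1)) stop("all size parameters must be positive")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)")
  }
  class(cfg) <- "vf_classifier_config"
  cfg
}

#' Build the convolutional-recurrent classifier
#'
#' Instantiates the layer stack: a trainable embedding layer whose rows are
#' initialized from corpus-trained skip-gram vectors (random uniform for
#' tokens without a pretrained vector; an all-zero row for padding), 20%
#' dropout, a 1-D convolution (64 filters, kernel 5, ReLU), max pooling of
#' window 4, a 100-unit LSTM, and a single sigmoid unit. Weight
#' initialization is Glorot-uniform for the convolution, dense and LSTM
#' input weights, per-gate orthogonal for the LSTM recurrent weights, with
#' the LSTM forget-gate bias set to 1.
#'
#' @param vocab_map named integer vector mapping training tokens to indices
#'   `1..V` (build with [build_vocab_map()]).
#' @param init_vectors a `vf_embeddings` used to initialize embedding rows;
#'   its dimension must equal `cfg$embedding_dim`.
#' @param cfg a [classifier_config()].
#' @return An untrained `vf_classifier` with a `layers` description usable
#'   for architecture introspection.
#' @export
build_model <- function(vocab_map, init_vectors, cfg = classifier_config()) {
  if (!is.null(init_vectors) && init_vectors$dim != cfg$embedding_dim) {
    stop("embedding dimension mismatch: vectors are ", init_vectors$dim,
         "-d but cfg$embedding_dim is ", cfg$embedding_dim)
  }
  set.seed(cfg$seed)
  V <- length(vocab_map)
  D <- cfg$embedding_dim; K <- cfg$kernel_size; Fn <- cfg$conv_filters
  H <- cfg$lstm_units
  n_rows <- V + 2L                      # PAD row 1, UNK row 2, tokens 3..V+2
  E <- matrix(stats::runif(n_rows * D, -0.05, 0.05), nrow = n_rows)
  E[1L, ] <- 0
  if (!is.null(init_vectors)) {
    for (tok in names(vocab_map)) {
      vec <- embedding_vector(init_vectors, tok)
      if (!is.null(vec)) E[vocab_map[[tok]] + 2L, ] <- vec
    }
  }
  glorot <- function(nin, nout, nr, nc) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nr * nc, -lim, lim), nrow = nr)
  }
  orth <- function(n) qr.Q(qr(matrix(stats::rnorm(n * n), n)))
  Wc <- glorot(K * D, Fn, K * D, Fn)
  bc <- numeric(Fn)
  Wx <- glorot(Fn, 4 * H, Fn, 4 * H)
  Wh <- do.call(cbind, lapply(1:4, function(i) orth(H)))
  bl <- numeric(4 * H); bl[(H + 1L):(2L * H)] <- 1   # forget bias
  Wd <- glorot(H, 1, H, 1)
  bd <- 0
  layers <- list(
    list(type = "embedding", input_dim = n_rows, output_dim = D, trainable = TRUE),
    list(type = "dropout", rate = cfg$dropout_rate),
    list(type = "conv1d", filters = Fn, kernel_size = K, activation = "relu"),
    list(type = "max_pooling1d", pool_size = cfg$pool_size),
    list(type = "lstm", units = H),
    list(type = "dense", units = 1L, activation = "sigmoid")
  )
  structure(list(
    cfg = cfg, vocab_map = vocab_map, layers = layers,
    params = list(E = E, Wc = Wc, bc = bc, Wx = Wx, Wh = Wh, bl = bl,
                  Wd = Wd, bd = bd),
    trained = FALSE
  ), class = "vf_classifier")
}

#' @export
print.vf_classifier <- function(x, ...) {
  cat("<vf_classifier>", if (x$trained) "trained" else "untrained", "\n")
  for (l in x$layers) {
    cat("  ", paste(names(l), unlist(l), sep = "=", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Build a token-index map from cleaned training texts
#'
#' @param texts character vector of cleaned narratives.
#' @return Named integer vector token -> index `1..V` (sorted tokens).
#' @export
build_vocab_map <- function(texts) {
  toks <- sort(unique(unlist(lapply(texts, function(t) as.character(tokenize(t))))))
  idx <- seq_along(toks)
  names(idx) <- toks
  idx
}

# texts -> integer matrix B x T of embedding row indices (1 = PAD, 2 = UNK)
.encode_texts <- function(texts, vocab_map, max_len) {
  B <- length(texts)
  X <- matrix(1L, nrow = B, ncol = max_len)
  for (b in seq_len(B)) {
    toks <- as.character(tokenize(texts[b]))
    if (length(toks) == 0L) next
    toks <- toks[seq_len(min(length(toks), max_len))]   # truncate post
    ids <- unname(vocab_map[toks])
    ids <- ifelse(is.na(ids), 2L, ids + 2L)
    X[b, seq_along(ids)] <- ids                          # pad post
  }
  X
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; returns prediction and (if keep = TRUE) the cache for BPTT
.forward <- function(model, X, training = FALSE, keep = FALSE) {
  p <- model$params; cfg <- model$cfg
  B <- nrow(X); Tn <- ncol(X); D <- cfg$embedding_dim
  K <- cfg$kernel_size; Fn <- cfg$conv_filters; H <- cfg$lstm_units
  L <- Tn - K + 1L
  P <- L %/% cfg$pool_size
  if (L < 1L || P < 1L) stop("max_sequence_length too short for kernel/pool sizes")
  flat <- as.vector(X)                          # column-major: (b, t) -> b + B(t-1)
  M0 <- p$E[flat, , drop = FALSE]               # (B*T) x D
  drop_mask <- NULL
  if (training && cfg$dropout_rate > 0) {
    drop_mask <- matrix(stats::runif(length(M0)) >= cfg$dropout_rate,
                        nrow = nrow(M0)) / (1 - cfg$dropout_rate)
    M0 <- M0 * drop_mask
  }
  # im2col: row (b, l) of Mc gathers embedding rows (b, l) .. (b, l+K-1)
  bl <- rep(seq_len(B), times = L)
  ll <- rep(seq_len(L), each = B)
  Mc <- matrix(0, nrow = B * L, ncol = K * D)
  row_idx <- vector("list", K)
  for (k in seq_len(K)) {
    ri <- bl + B * (ll + k - 2L)
    row_idx[[k]] <- ri
    Mc[, ((k - 1L) * D + 1L):(k * D)] <- M0[ri, , drop = FALSE]
  }
  Z <- sweep(Mc %*% p$Wc, 2L, p$bc, "+")        # (B*L) x F
  A <- pmax(Z, 0)
  # max pooling over windows of pool_size along l
  pooled <- vector("list", P)
  argmax <- vector("list", P)
  for (q in seq_len(P)) {
    ls <- ((q - 1L) * cfg$pool_size + 1L):(q * cfg$pool_size)
    mx <- matrix(-Inf, nrow = B, ncol = Fn)
    am <- matrix(ls[1L], nrow = B, ncol = Fn)
    for (l in ls) {
      rows <- (l - 1L) * B + seq_len(B)
      Al <- A[rows, , drop = FALSE]
      upd <- Al > mx
      am[upd] <- l
      mx[upd] <- Al[upd]
    }
    pooled[[q]] <- mx
    argmax[[q]] <- am
  }
  # LSTM over P steps
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  gates <- vector("list", P); cells <- vector("list", P)
  hs <- vector("list", P); xs <- pooled
  for (q in seq_len(P)) {
    z <- sweep(xs[[q]] %*% p$Wx + h %*% p$Wh, 2L, p$bl, "+")
    i <- .sigmoid(z[, 1:H, drop = FALSE])
    f <- .sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    gates[[q]] <- list(i = i, f = f, g = g, o = o, tc = tc, c_prev = c_prev)
    cells[[q]] <- cc
    hs[[q]] <- h
  }
  logit <- drop(h %*% p$Wd) + p$bd
  prob <- .sigmoid(logit)
  res <- list(prob = prob)
  if (keep) {
    res$cache <- list(X = X, flat = flat, M0 = M0, drop_mask = drop_mask,
                      Mc = Mc, row_idx = row_idx, Z = Z, A = A,
                      pooled = pooled, argmax = argmax, gates = gates,
                      cells = cells, hs = hs, bl_vec = bl, ll_vec = ll,
                      B = B, Tn = Tn, L = L, P = P)
  }
  res
}

# backward pass; returns gradients for all parameter tensors
.backward <- function(model, cache, prob, y, sample_w) {
  p <- model$params; cfg <- model$cfg
  B <- cache$B; D <- cfg$embedding_dim; K <- cfg$kernel_size
  Fn <- cfg$conv_filters; H <- cfg$lstm_units
  L <- cache$L; P <- cache$P
  w <- sample_w / sum(sample_w)
  dlogit <- (prob - y) * w                      # B, weighted BCE with sigmoid
  hT <- cache$hs[[P]]
  gWd <- crossprod(hT, dlogit)
  gbd <- sum(dlogit)
  dh <- dlogit %*% t(p$Wd)                      # B x H
  dc <- matrix(0, B, H)
  gWx <- matrix(0, Fn, 4 * H); gWh <- matrix(0, H, 4 * H); gbl <- numeric(4 * H)
  dxs <- vector("list", P)
  for (q in rev(seq_len(P))) {
    gt <- cache$gates[[q]]
    do_ <- dh * gt$tc
    dct <- dh * gt$o * (1 - gt$tc^2) + dc
    di <- dct * gt$g
    dg <- dct * gt$i
    df <- dct * gt$c_prev
    dc <- dct * gt$f
    dzi <- di * gt$i * (1 - gt$i)
    dzf <- df * gt$f * (1 - gt$f)
    dzg <- dg * (1 - gt$g^2)
    dzo <- do_ * gt$o * (1 - gt$o)
    dz <- cbind(dzi, dzf, dzg, dzo)             # B x 4H
    h_prev <- if (q > 1L) cache$hs[[q - 1L]] else matrix(0, B, H)
    gWx <- gWx + crossprod(cache$pooled[[q]], dz)
    gWh <- gWh + crossprod(h_prev, dz)
    gbl <- gbl + colSums(dz)
    dxs[[q]] <- dz %*% t(p$Wx)
    dh <- dz %*% t(p$Wh)
  }
  # maxpool backward: scatter dxs into dA at argmax rows
  dA <- matrix(0, nrow = B * L, ncol = Fn)
  bcol <- seq_len(B)
  for (q in seq_len(P)) {
    am <- cache$argmax[[q]]                     # B x F of l positions
    dx <- dxs[[q]]
    for (f in seq_len(Fn)) {
      rows <- (am[, f] - 1L) * B + bcol
      dA[cbind(rows, f)] <- dA[cbind(rows, f)] + dx[, f]
    }
  }
  dZ <- dA * (cache$Z > 0)
  gWc <- crossprod(cache$Mc, dZ)
  gbc <- colSums(dZ)
  dMc <- dZ %*% t(p$Wc)                         # (B*L) x (K*D)
  dM0 <- matrix(0, nrow = B * cache$Tn, ncol = D)
  for (k in seq_len(K)) {
    ri <- cache$row_idx[[k]]                    # no duplicates within one k
    dM0[ri, ] <- dM0[ri, , drop = FALSE] + dMc[, ((k - 1L) * D + 1L):(k * D), drop = FALSE]
  }
  if (!is.null(cache$drop_mask)) dM0 <- dM0 * cache$drop_mask
  agg <- rowsum(dM0, group = cache$flat)
  gE_rows <- as.integer(rownames(agg))
  list(gWd = gWd, gbd = gbd, gWx = gWx, gWh = gWh, gbl = gbl,
       gWc = gWc, gbc = gbc, gE = agg, gE_rows = gE_rows)
}

.adam_init <- function(params) {
  lapply(params, function(x) list(m = x * 0, v = x * 0))
}

.adam_step <- function(x, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(x = x - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train the classifier
#'
#' Adam optimization of the binary cross-entropy loss, with a stratified
#' 80:20 train/validation split (class ratio preserved within one record
#' per class), per-epoch validation loss and per-class F1, and early
#' stopping on validation loss with best-weight restoration. Fully
#' reproducible on a single device under `cfg$seed`.
#'
#' @param model an untrained `vf_classifier` from [build_model()].
#' @param texts character vector of cleaned narratives.
#' @param labels character vector of `"V"`/`"NV"` gold labels.
#' @return The trained `vf_classifier`, with a `history` data frame
#'   (epoch, train_loss, val_loss, val_f1_v, val_f1_nv) and `val_report`
#'   (the [classification_metrics()] of the best epoch's validation split).
#' @export
train_classifier <- function(model, texts, labels) {
  cfg <- model$cfg
  stopifnot(length(texts) == length(labels))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes (V and NV)")
  }
  if (min(table(labels)) < 2L) stop("need at least two records per class")
  y_all <- as.numeric(labels == "V")
  set.seed(cfg$seed + 1L)
  # stratified split
  idx_v <- which(y_all == 1); idx_n <- which(y_all == 0)
  n_val_v <- round(length(idx_v) * cfg$validation_split)
  n_val_n <- round(length(idx_n) * cfg$validation_split)
  val_idx <- c(sample(idx_v, n_val_v), sample(idx_n, n_val_n))
  tr_idx <- setdiff(seq_along(y_all), val_idx)
  X_tr <- .encode_texts(texts[tr_idx], model$vocab_map, cfg$max_sequence_length)
  X_va <- .encode_texts(texts[val_idx], model$vocab_map, cfg$max_sequence_length)
  y_tr <- y_all[tr_idx]; y_va <- y_all[val_idx]
  w_of <- function(y) {
    if (is.null(cfg$class_weight)) rep(1, length(y))
    else ifelse(y == 1, cfg$class_weight[["V"]], cfg$class_weight[["NV"]])
  }
  adam <- .adam_init(model$params)
  t_step <- 0L
  best <- list(loss = Inf, params = model$params, epoch = 0L, report = NULL)
  wait <- 0L
  history <- NULL
  n_tr <- length(tr_idx)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, n_tr, by = cfg$batch_size)) {
      sel <- ord[start:min(start + cfg$batch_size - 1L, n_tr)]
      Xb <- X_tr[sel, , drop = FALSE]; yb <- y_tr[sel]; wb <- w_of(yb)
      fw <- .forward(model, Xb, training = TRUE, keep = TRUE)
      pr <- pmin(pmax(fw$prob, 1e-7), 1 - 1e-7)
      loss <- -sum(wb * (yb * log(pr) + (1 - yb) * log(1 - pr))) / sum(wb)
      ep_loss <- ep_loss + loss * length(sel); ep_n <- ep_n + length(sel)
      gr <- .backward(model, fw$cache, fw$prob, yb, wb)
      t_step <- t_step + 1L
      for (nm in c("Wd", "bd", "Wx", "Wh", "bl", "Wc", "bc")) {
        gname <- paste0("g", nm)
        res <- .adam_step(model$params[[nm]], gr[[gname]], adam[[nm]],
                          cfg$learning_rate, t_step)
        model$params[[nm]] <- res$x
        adam[[nm]] <- res$st
      }
      # sparse Adam on touched embedding rows; PAD row stays zero
      rows <- setdiff(gr$gE_rows, 1L)
      if (length(rows) > 0L) {
        gmap <- match(rows, gr$gE_rows)
        gsub_ <- gr$gE[gmap, , drop = FALSE]
        stE <- adam$E
        stE$m[rows, ] <- 0.9 * stE$m[rows, , drop = FALSE] + 0.1 * gsub_
        stE$v[rows, ] <- 0.999 * stE$v[rows, , drop = FALSE] + 0.001 * gsub_^2
        mh <- stE$m[rows, , drop = FALSE] / (1 - 0.9^t_step)
        vh <- stE$v[rows, , drop = FALSE] / (1 - 0.999^t_step)
        model$params$E[rows, ] <- model$params$E[rows, , drop = FALSE] -
          cfg$learning_rate * mh / (sqrt(vh) + 1e-8)
        adam$E <- stE
      }
    }
    va <- .forward(model, X_va)
    pv <- pmin(pmax(va$prob, 1e-7), 1 - 1e-7)
    wv <- w_of(y_va)
    val_loss <- -sum(wv * (y_va * log(pv) + (1 - y_va) * log(1 - pv))) / sum(wv)
    pred_lab <- ifelse(va$prob >= cfg$threshold, "V", "NV")
    gold_lab <- ifelse(y_va == 1, "V", "NV")
    rep_ <- classification_metrics(
      data.frame(id = seq_along(pred_lab), label = pred_lab),
      data.frame(id = seq_along(gold_lab), label = gold_lab))
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = ep_loss / ep_n, val_loss = val_loss,
      val_f1_v = rep_$per_class["V", "f1"], val_f1_nv = rep_$per_class["NV", "f1"]))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = model$params, epoch = ep, report = rep_)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best$epoch
  model$val_report <- best$report
  model$val_prevalence <- mean(y_va)
  model
}

#' Predict labels for cleaned records
#'
#' Uses the same tokenization as the training path, pads/truncates to the
#' configured sequence length, and thresholds the sigmoid output at
#' `cfg$threshold` (default 0.5). Empty texts yield the all-padding
#' prediction rather than an error. Inference is deterministic (dropout
#' off).
#'
#' @param model a trained `vf_classifier`.
#' @param texts character vector of cleaned narratives.
#' @param ids optional record identifiers (default positional).
#' @return Data frame with columns `id`, `probability`, `label`.
#' @export
predict_label <- function(model, texts, ids = seq_along(texts)) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  X <- .encode_texts(texts, model$vocab_map, model$cfg$max_sequence_length)
  prob <- numeric(0)
  bs <- 256L
  for (start in seq(1L, nrow(X), by = bs)) {
    sel <- start:min(start + bs - 1L, nrow(X))
    prob <- c(prob, .forward(model, X[sel, , drop = FALSE])$prob)
  }
  data.frame(id = as.character(ids), probability = prob,
             label = ifelse(prob >= model$cfg$threshold, "V", "NV"),
             stringsAsFactors = FALSE)
}
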