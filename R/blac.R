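#' BLAC architecture specification
#'
#' Hidden sizes of the recurrent attention classifier: two stacked
#' bidirectional LSTM layers, a time-distributed dense layer and an additive
#' attention layer. Defaults (64, 64, 32, 32) suit corpus-scale runs; tests
#' and the synthetic studies use smaller widths.
#'
#' @param lstm1_units,lstm2_units per-direction LSTM hidden sizes
#' @param td_dense_units width of the time-distributed dense layer
#' @param attention_dim projection size of the additive attention scorer
#' @return list of class `blac_arch`
#' @export
blac_arch <- function(lstm1_units = 64L, lstm2_units = 64L,
                      td_dense_units = 32L, attention_dim = 32L) {
  stopifnot(lstm1_units > 0, lstm2_units > 0, td_dense_units > 0,
            attention_dim > 0)
  structure(list(lstm1_units = lstm1_units, lstm2_units = lstm2_units,
                 td_dense_units = td_dense_units,
                 attention_dim = attention_dim), class = "blac_arch")
}

#' Build a BLAC model
#'
#' Layer order: frozen embedding -> biLSTM1 -> batchnorm -> biLSTM2 ->
#' batchnorm -> time-distributed dense (tanh) -> batchnorm -> additive
#' attention (softmax-weighted sum over time) -> dense sigmoid scalar. The
#' embedding rows are fixed; only the downstream layers train. Sequences of
#' any length are accepted; padded positions contribute nothing to the
#' recurrences, the batch statistics, the attention weights or the loss.
#'
#' @param emb a `crcs_embedding` (frozen lookup table)
#' @param arch a [blac_arch()]
#' @param dict optional `switch_dictionary`; when given, its ordering
#'   fingerprint must match the one stored on `emb`
#' @param seed seed for the random initialization
#' @return object of class `blac_model`
#' @export
build_blac <- function(emb, arch = blac_arch(), dict = NULL, seed = 1L) {
  if (!is.null(dict) && !is.na(emb$dict_fingerprint) &&
      !identical(emb$dict_fingerprint, dict_fingerprint(dict)))
    crcs_stop("embedding fingerprint %s does not match dictionary %s",
              "crcs_validation_error", emb$dict_fingerprint,
              dict_fingerprint(dict))
  set.seed(seed)
  L <- emb$L
  u1 <- arch$lstm1_units; u2 <- arch$lstm2_units
  dtd <- arch$td_dense_units; da <- arch$attention_dim
  l1f <- lstm_init(L, u1); l1b <- lstm_init(L, u1)
  l2f <- lstm_init(2 * u1, u2); l2b <- lstm_init(2 * u1, u2)
  bn1 <- bn_init(2 * u1); bn2 <- bn_init(2 * u2); bn3 <- bn_init(dtd)
  at <- attn_init(dtd, da)
  params <- list(
    l1f.Wx = l1f$Wx, l1f.Wh = l1f$Wh, l1f.b = l1f$b,
    l1b.Wx = l1b$Wx, l1b.Wh = l1b$Wh, l1b.b = l1b$b,
    bn1.gamma = bn1$gamma, bn1.beta = bn1$beta,
    l2f.Wx = l2f$Wx, l2f.Wh = l2f$Wh, l2f.b = l2f$b,
    l2b.Wx = l2b$Wx, l2b.Wh = l2b$Wh, l2b.b = l2b$b,
    bn2.gamma = bn2$gamma, bn2.beta = bn2$beta,
    td.W = glorot(2 * u2, dtd), td.b = rep(0, dtd),
    bn3.gamma = bn3$gamma, bn3.beta = bn3$beta,
    at.Wa = at$Wa, at.ba = at$ba, at.v = at$v,
    out.W = stats::runif(dtd, -0.1, 0.1), out.b = 0)
  stats_ <- list(
    bn1 = list(run_mean = bn1$run_mean, run_var = bn1$run_var),
    bn2 = list(run_mean = bn2$run_mean, run_var = bn2$run_var),
    bn3 = list(run_mean = bn3$run_mean, run_var = bn3$run_var))
  structure(list(emb = emb$values, L = L, arch = arch, params = params,
                 bn_stats = stats_,
                 dict_fingerprint = emb$dict_fingerprint),
            class = "blac_model")
}

#' @export
print.blac_model <- function(x, ...) {
  cat(sprintf(
    "<blac_model L=%d, biLSTM %d/%d, td %d, attn %d; %d trainable params>\n",
    x$L, x$arch$lstm1_units, x$arch$lstm2_units, x$arch$td_dense_units,
    x$arch$attention_dim, n_trainable(x)))
  invisible(x)
}

bn_params <- function(model, name) {
  list(gamma = model$params[[paste0(name, ".gamma")]],
       beta = model$params[[paste0(name, ".beta")]],
       run_mean = model$bn_stats[[name]]$run_mean,
       run_var = model$bn_stats[[name]]$run_var)
}

lstm_params <- function(model, name) {
  list(Wx = model$params[[paste0(name, ".Wx")]],
       Wh = model$params[[paste0(name, ".Wh")]],
       b = model$params[[paste0(name, ".b")]])
}

# Forward pass over one padded batch. idx_list: list of 0-based switch index
# vectors. Returns probabilities, cache (train mode) and updated BN stats.
blac_forward_batch <- function(model, idx_list, train = TRUE) {
  B <- length(idx_list)
  lens <- lengths(idx_list)
  T_ <- max(lens)
  mask <- matrix(0, B, T_)
  for (i in seq_len(B)) mask[i, seq_len(lens[i])] <- 1
  X <- vector("list", T_)
  for (t in seq_len(T_)) {
    rows <- vapply(idx_list, function(s) if (t <= length(s)) s[t] + 1L else 1L,
                   integer(1))
    X[[t]] <- model$emb[rows, , drop = FALSE]
  }
  f1 <- lstm_forward(X, mask, lstm_params(model, "l1f"), reverse = FALSE)
  b1 <- lstm_forward(X, mask, lstm_params(model, "l1b"), reverse = TRUE)
  H1 <- lapply(seq_len(T_), function(t) cbind(f1$H[[t]], b1$H[[t]]))
  n1 <- bn_forward(H1, mask, bn_params(model, "bn1"), train = train)
  f2 <- lstm_forward(n1$Y, mask, lstm_params(model, "l2f"), reverse = FALSE)
  b2 <- lstm_forward(n1$Y, mask, lstm_params(model, "l2b"), reverse = TRUE)
  H2 <- lapply(seq_len(T_), function(t) cbind(f2$H[[t]], b2$H[[t]]))
  n2 <- bn_forward(H2, mask, bn_params(model, "bn2"), train = train)
  td <- lapply(n2$Y, function(y)
    tanh(y %*% model$params$td.W +
           matrix(model$params$td.b, nrow(y), length(model$params$td.b),
                  byrow = TRUE)))
  n3 <- bn_forward(td, mask, bn_params(model, "bn3"), train = train)
  at <- attn_forward(n3$Y, mask, list(Wa = model$params$at.Wa,
                                      ba = model$params$at.ba,
                                      v = model$params$at.v))
  z <- as.vector(at$context %*% model$params$out.W) + model$params$out.b
  p <- sigmoid(z)
  list(p = p,
       bn_stats = list(bn1 = list(run_mean = n1$P$run_mean,
                                  run_var = n1$P$run_var),
                       bn2 = list(run_mean = n2$P$run_mean,
                                  run_var = n2$P$run_var),
                       bn3 = list(run_mean = n3$P$run_mean,
                                  run_var = n3$P$run_var)),
       cache = list(mask = mask, f1 = f1, b1 = b1, n1 = n1, f2 = f2, b2 = b2,
                    n2 = n2, td = td, n3 = n3, at = at,
                    context = at$context, p = p))
}

# Gradients of mean BCE over one batch w.r.t. every trainable parameter.
blac_backward_batch <- function(model, cache, labels) {
  B <- length(labels)
  T_ <- ncol(cache$mask)
  u2 <- model$arch$lstm2_units
  dz <- (cache$p - labels) / B
  g <- list()
  g$out.W <- as.vector(t(cache$context) %*% dz)
  g$out.b <- sum(dz)
  dctx <- outer(dz, model$params$out.W)
  ab <- attn_backward(dctx, cache$at$cache)
  g$at.Wa <- ab$dWa; g$at.ba <- ab$dba; g$at.v <- ab$dv
  n3b <- bn_backward(ab$dX, cache$n3$cache)
  g$bn3.gamma <- n3b$dgamma; g$bn3.beta <- n3b$dbeta
  # through td tanh dense
  dtdW <- model$params$td.W * 0; dtdb <- model$params$td.b * 0
  dN2 <- vector("list", T_)
  for (t in seq_len(T_)) {
    dpre <- n3b$dX[[t]] * (1 - cache$td[[t]]^2)
    dtdW <- dtdW + t(cache$n2$Y[[t]]) %*% dpre
    dtdb <- dtdb + colSums(dpre)
    dN2[[t]] <- dpre %*% t(model$params$td.W)
  }
  g$td.W <- dtdW; g$td.b <- dtdb
  n2b <- bn_backward(dN2, cache$n2$cache)
  g$bn2.gamma <- n2b$dgamma; g$bn2.beta <- n2b$dbeta
  dH2f <- lapply(n2b$dX, function(m) m[, 1:u2, drop = FALSE])
  dH2b <- lapply(n2b$dX, function(m) m[, (u2 + 1):(2 * u2), drop = FALSE])
  l2fb <- lstm_backward(dH2f, cache$f2)
  l2bb <- lstm_backward(dH2b, cache$b2)
  g$l2f.Wx <- l2fb$dWx; g$l2f.Wh <- l2fb$dWh; g$l2f.b <- l2fb$db
  g$l2b.Wx <- l2bb$dWx; g$l2b.Wh <- l2bb$dWh; g$l2b.b <- l2bb$db
  dN1 <- lapply(seq_len(T_), function(t) l2fb$dX[[t]] + l2bb$dX[[t]])
  n1b <- bn_backward(dN1, cache$n1$cache)
  g$bn1.gamma <- n1b$dgamma; g$bn1.beta <- n1b$dbeta
  u1 <- model$arch$lstm1_units
  dH1f <- lapply(n1b$dX, function(m) m[, 1:u1, drop = FALSE])
  dH1b <- lapply(n1b$dX, function(m) m[, (u1 + 1):(2 * u1), drop = FALSE])
  l1fb <- lstm_backward(dH1f, cache$f1)
  l1bb <- lstm_backward(dH1b, cache$b1)
  g$l1f.Wx <- l1fb$dWx; g$l1f.Wh <- l1fb$dWh; g$l1f.b <- l1fb$db
  g$l1b.Wx <- l1bb$dWx; g$l1b.Wh <- l1bb$dWh; g$l1b.b <- l1bb$db
  g[names(model$params)]
}

blac_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# length-bucketed batches: indices grouped after sorting by sequence length
make_batches <- function(seqs, batch_size) {
  ord <- order(lengths(seqs))
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Fit a BLAC model on labeled switch sequences
#'
#' Minimizes binary cross-entropy with ADAM over length-bucketed, padded
#' mini-batches (padding is masked out of every layer). The embedding matrix
#' is never updated.
#'
#' @param model a `blac_model` from [build_blac()]
#' @param seqs list of `switch_seq` (or integer index vectors)
#' @param labels binary vector
#' @param epochs,batch_size,lr training schedule
#' @param seed seed for batch shuffling
#' @return the trained model; per-epoch loss in attribute `loss`
#' @export
blac_fit <- function(model, seqs, labels, epochs = 30L, batch_size = 32L,
                     lr = 3e-3, seed = 1L) {
  if (length(unique(labels)) < 2L)
    crcs_stop("training labels are single-class", "crcs_validation_error")
  idx_list <- lapply(seqs, seq_indices)
  batches <- make_batches(idx_list, batch_size)
  opt <- adam_init(model$params, lr = lr)
  set.seed(seed)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tot <- 0; nseen <- 0
    for (bi in sample(seq_along(batches))) {
      rows <- batches[[bi]]
      fwd <- blac_forward_batch(model, idx_list[rows], train = TRUE)
      model$bn_stats <- fwd$bn_stats
      tot <- tot + blac_loss(fwd$p, labels[rows]) * length(rows)
      nseen <- nseen + length(rows)
      grads <- blac_backward_batch(model, fwd$cache, labels[rows])
      upd <- adam_step(opt, grads)
      opt <- upd$opt
      for (k in names(model$params))
        model$params[[k]] <- model$params[[k]] - upd$delta[[k]]
    }
    losses[ep] <- tot / nseen
  }
  attr(model, "loss") <- losses
  model
}

#' Score switch sequences with a trained BLAC
#'
#' Runs the network in inference mode (batch normalization uses its running
#' statistics).
#' @param model a trained `blac_model`
#' @param seqs list of `switch_seq` or integer index vectors
#' @param batch_size batch size
#' @return numeric vector of probabilities in \[0, 1\]
#' @export
predict_blac <- function(model, seqs, batch_size = 64L) {
  idx_list <- lapply(seqs, seq_indices)
  out <- numeric(length(idx_list))
  for (rows in make_batches(idx_list, batch_size)) {
    fwd <- blac_forward_batch(model, idx_list[rows], train = FALSE)
    out[rows] <- fwd$p
  }
  out
}

#' Training-set filters for classification
#'
#' Keeps sequences strictly shorter than `max_len` codon switches, then
#' keeps only genes contributing at least `min_gene_variants` sequences
#' (splice variants counted individually).
#'
#' @param seqs list of `switch_seq`
#' @param max_len length cap (default 1500, strict `<`)
#' @param min_gene_variants minimum sequences per retained gene (default 200)
#' @return filtered list
#' @export
filter_training_set <- function(seqs, max_len = 1500L,
                                min_gene_variants = 200L) {
  if (length(seqs) == 0L) return(seqs)
  keep <- lengths(lapply(seqs, seq_indices)) < max_len
  seqs <- seqs[keep]
  if (length(seqs) == 0L) return(seqs)
  genes <- vapply(seqs, function(s) s$gene_symbol, character(1))
  tab <- table(genes)
  seqs[genes %in% names(tab)[tab >= min_gene_variants]]
}

#' Gene-disjoint fold assignment
#'
#' Partitions genes into `k` folds of near-equal size (differing by at most
#' one gene), deterministically for a given seed. No gene can then appear in
#' both the training and validation split of any fold.
#'
#' @param genes character vector of gene symbols (deduplicated internally)
#' @param k number of folds
#' @param seed shuffle seed
#' @return named integer vector gene -> fold id (1..k)
#' @export
assign_gene_folds <- function(genes, k = 4L, seed = 1L) {
  genes <- unique(genes)
  if (length(genes) < k)
    crcs_stop("%d genes cannot fill %d folds", "crcs_validation_error",
              length(genes), k)
  set.seed(seed)
  shuffled <- sample(genes)
  stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
}

#' Gene-disjoint cross-validated BLAC training
#'
#' Trains one model per fold on the sequences of all other folds' genes and
#' scores each sequence exactly once, by the model whose training set
#' excluded its gene.
#'
#' @param seqs list of `switch_seq` carrying gene symbols
#' @param labels binary vector (1 = cancer-like class)
#' @param emb a `crcs_embedding`
#' @param arch a [blac_arch()]
#' @param folds number of folds (default 4)
#' @param epochs,batch_size,lr training schedule per fold
#' @param seed seed controlling fold assignment, initialization and shuffling
#' @param keep_models keep the per-fold models on the result (default TRUE)
#' @return object of class `blac_cv`: `scores` data.frame (variant_key,
#'   transcript_id, gene, label, fold, score), per-fold average precision
#'   `fold_ap`, overall `ap`, `fold_assignment`, and optionally `models`
#' @export
train_blac <- function(seqs, labels, emb, arch = blac_arch(), folds = 4L,
                       epochs = 30L, batch_size = 32L, lr = 3e-3, seed = 1L,
                       keep_models = TRUE) {
  stopifnot(length(seqs) == length(labels))
  genes <- vapply(seqs, function(s) s$gene_symbol, character(1))
  fold_of_gene <- assign_gene_folds(genes, k = folds, seed = seed)
  fold <- unname(fold_of_gene[genes])
  models <- vector("list", folds)
  rows <- list()
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    va <- which(fold == f)
    if (length(va) == 0L) next
    if (length(unique(labels[tr])) < 2L)
      crcs_stop("fold %d training split is single-class",
                "crcs_validation_error", f)
    stopifnot(length(intersect(genes[tr], genes[va])) == 0L)
    model <- build_blac(emb, arch, seed = seed + f)
    model <- blac_fit(model, seqs[tr], labels[tr], epochs = epochs,
                      batch_size = batch_size, lr = lr, seed = seed + f)
    sc <- predict_blac(model, seqs[va])
    rows[[f]] <- data.frame(
      variant_key = vapply(seqs[va], function(s)
        if (is.na(s$variant_key)) "" else s$variant_key, character(1)),
      transcript_id = vapply(seqs[va], function(s) s$transcript_id,
                             character(1)),
      gene = genes[va], label = labels[va], fold = f, score = sc,
      stringsAsFactors = FALSE)
    if (keep_models) models[[f]] <- model
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  fold_ap <- vapply(seq_len(folds), function(f) {
    s <- scores[scores$fold == f, ]
    if (nrow(s) == 0L || sum(s$label) == 0L) return(NA_real_)
    average_precision(s$score, s$label)
  }, numeric(1))
  structure(list(scores = scores, fold_ap = fold_ap,
                 ap = average_precision(scores$score, scores$label),
                 fold_assignment = fold_of_gene,
                 models = if (keep_models) models else NULL),
            class = "blac_cv")
}

#' @export
print.blac_cv <- function(x, ...) {
  cat(sprintf("<blac_cv %d sequences, out-of-fold AP %.3f (folds: %s)>\n",
              nrow(x$scores), x$ap,
              paste(sprintf("%.3f", x$fold_ap), collapse = ", ")))
  invisible(x)
}

#' Fake-split control experiment
#'
#' Randomly halves a single-class sequence pool into two balanced
#' pseudo-classes and runs the full gene-disjoint cross-validated training
#' and scoring cycle. With no real signal the out-of-fold average precision
#' should scatter around the positive prevalence, 0.5.
#'
#' @param seqs homogeneous pool of `switch_seq`
#' @param emb a `crcs_embedding`
#' @param arch a [blac_arch()]
#' @param folds,epochs,batch_size,lr training schedule
#' @param seed seed for the pseudo-split and training
#' @return the out-of-fold average precision; the full `blac_cv` is attached
#'   as attribute `cv`
#' @export
fake_split_control <- function(seqs, emb, arch = blac_arch(), folds = 4L,
                               epochs = 30L, batch_size = 32L, lr = 3e-3,
                               seed = 1L) {
  if (length(seqs) < 4L * folds)
    crcs_stop("pool of %d sequences is too small for %d folds",
              "crcs_validation_error", length(seqs), folds)
  set.seed(seed)
  labels <- rep(0L, length(seqs))
  labels[sample.int(length(seqs), floor(length(seqs) / 2))] <- 1L
  cv <- train_blac(seqs, labels, emb, arch, folds = folds, epochs = epochs,
                   batch_size = batch_size, lr = lr, seed = seed,
                   keep_models = FALSE)
  structure(cv$ap, cv = cv)
}
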