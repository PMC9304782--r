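#' Embedding matrix container
#'
#' @param values 640 x L numeric matrix (row i = switch index i-1)
#' @param chromosome_tag free-text tag of the sequence set the embedding was
#'   trained on (embeddings are chromosome-specific)
#' @param dict_fingerprint fingerprint of the dictionary ordering the row
#'   indices refer to
#' @return object of class `crcs_embedding`
#' @export
crcs_embedding <- function(values, chromosome_tag = "NA",
                           dict_fingerprint = NA_character_) {
  if (nrow(values) != 640L)
    crcs_stop("embedding matrix must have 640 rows", "crcs_validation_error")
  if (!all(is.finite(values)))
    crcs_stop("embedding matrix has non-finite entries",
              "crcs_validation_error")
  structure(list(values = values, L = ncol(values),
                 chromosome_tag = chromosome_tag,
                 dict_fingerprint = dict_fingerprint),
            class = "crcs_embedding")
}

#' @export
print.crcs_embedding <- function(x, ...) {
  cat(sprintf("<crcs_embedding 640 x %d, tag=%s, dict=%s>\n", x$L,
              x$chromosome_tag, x$dict_fingerprint))
  invisible(x)
}

seq_indices <- function(x) {
  if (inherits(x, "switch_seq")) x$indices else as.integer(x)
}

#' Relative codon-switch frequencies of a corpus
#'
#' @param corpus list of `switch_seq` (or bare integer index vectors)
#' @return numeric vector of length 640; entry i is the relative frequency of
#'   switch index i-1 over all switch occurrences; sums to 1
#' @export
switch_frequencies <- function(corpus) {
  if (length(corpus) == 0L)
    crcs_stop("empty corpus", "crcs_empty_input")
  counts <- numeric(640L)
  for (s in corpus) {
    idx <- seq_indices(s)
    t <- tabulate(idx + 1L, nbins = 640L)
    counts <- counts + t
  }
  counts / sum(counts)
}

#' Subsampling keep probability for a codon-switch frequency
#'
#' The probability of selecting a codon switch as a training center is
#' min(1, sqrt(1 + f/eps) * eps / f): frequent switches (the identity
#' switches that dominate every sequence) are squeezed, rare ones kept.
#' An unseen switch (f = 0) is kept with probability 1 (the limit).
#'
#' @param f relative frequency (scalar or vector), nonnegative
#' @param epsilon frequency floor, default 0.001
#' @return keep probability in (0, 1]
#' @export
keep_probability <- function(f, epsilon = 0.001) {
  if (any(f < 0)) crcs_stop("negative frequency", "crcs_validation_error")
  p <- ifelse(f == 0, 1, pmin(1, sqrt(1 + f / epsilon) * epsilon / f))
  p
}

#' Select center positions of a sequence by frequency subsampling
#'
#' Each position is retained independently with the keep probability of its
#' switch's corpus frequency. Call `set.seed()` (or pass `seed`) for a
#' reproducible selection.
#'
#' @param seq a `switch_seq` or integer index vector
#' @param freqs length-640 frequency vector from [switch_frequencies()]
#' @param epsilon subsampling floor
#' @param seed optional seed
#' @return integer vector of selected positions (1-based)
#' @export
select_centers <- function(seq, freqs, epsilon = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- seq_indices(seq)
  p <- keep_probability(freqs[idx + 1L], epsilon)
  which(stats::runif(length(idx)) < p)
}

#' Build skip-gram tuples for selected centers
#'
#' For every center, one positive tuple per context switch within `ws`
#' positions on either side (truncated at the sequence ends), and
#' `ceiling((2 ws + 1) nsr)` negative tuples whose partners are drawn
#' uniformly from the whole 640-switch dictionary (collisions with true
#' context switches are not excluded).
#'
#' @param seq a `switch_seq` or integer index vector
#' @param centers 1-based positions from [select_centers()]
#' @param ws window size (default 3)
#' @param nsr negative sampling rate (default 0.2)
#' @param seed optional seed for the negative draws
#' @return data.frame with columns center, partner (switch indices 0..639)
#'   and label (1 = in-window, 0 = negative)
#' @export
make_tuples <- function(seq, centers, ws = 3L, nsr = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- seq_indices(seq)
  n <- length(idx)
  stopifnot(all(centers >= 1L & centers <= n))
  n_neg <- ceiling((2 * ws + 1) * nsr)
  cs <- integer(0); ps <- integer(0); ls <- integer(0)
  for (i in centers) {
    ctx <- setdiff(max(1L, i - ws):min(n, i + ws), i)
    cs <- c(cs, rep(idx[i], length(ctx)))
    ps <- c(ps, idx[ctx])
    ls <- c(ls, rep(1L, length(ctx)))
    if (n_neg > 0L) {
      cs <- c(cs, rep(idx[i], n_neg))
      ps <- c(ps, sample.int(640L, n_neg, replace = TRUE) - 1L)
      ls <- c(ls, rep(0L, n_neg))
    }
  }
  data.frame(center = cs, partner = ps, label = ls)
}

#' Subsample centers and build tuples over a whole corpus
#'
#' @param corpus list of `switch_seq`
#' @param ws,nsr,epsilon tuple-generation parameters
#' @param seed seed covering both the center selection and negative draws
#' @return data.frame of tuples (see [make_tuples()])
#' @export
generate_tuples <- function(corpus, ws = 3L, nsr = 0.2, epsilon = 0.001,
                            seed = 1L) {
  freqs <- switch_frequencies(corpus)
  set.seed(seed)
  parts <- lapply(corpus, function(s) {
    centers <- select_centers(s, freqs, epsilon)
    if (length(centers) == 0L) return(NULL)
    make_tuples(s, centers, ws = ws, nsr = nsr)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) data.frame(center = integer(0), partner = integer(0),
                               label = integer(0)) else out
}

#' Initialize the skip-gram embedding network
#'
#' One shared 640 x L embedding matrix serves both the center and partner
#' roles; the classification head applies a single dense unit (weight and
#' bias) to the dot product of the two embeddings, followed by a sigmoid.
#'
#' @param L embedding length (default 300)
#' @param V vocabulary size (640 codon switches)
#' @param seed seed for the random initialization
#' @return list with `E` (V x L), scalars `w`, `b`
#' @export
init_embedding_model <- function(L = 300L, V = 640L, seed = 1L) {
  set.seed(seed)
  list(E = matrix(stats::runif(V * L, -0.5, 0.5) / L, nrow = V), w = 1, b = 0)
}

#' Trainable parameter count of a model
#'
#' @param model a model object (embedding network or BLAC handle)
#' @return number of trainable scalars
#' @export
n_trainable <- function(model) {
  if (inherits(model, "blac_model"))
    return(sum(vapply(model$params, length, integer(1))))
  length(model$E) + length(model$w) + length(model$b)
}

# mean binary cross-entropy of the SGNS head and its analytic gradient
sgns_loss_and_grad <- function(model, center, partner, label) {
  n <- length(center)
  ec <- model$E[center + 1L, , drop = FALSE]
  ep <- model$E[partner + 1L, , drop = FALSE]
  dot <- rowSums(ec * ep)
  z <- model$w * dot + model$b
  p <- sigmoid(z)
  eps <- 1e-12
  loss <- -mean(label * log(p + eps) + (1 - label) * log(1 - p + eps))
  dz <- (p - label) / n
  dw <- sum(dz * dot)
  db <- sum(dz)
  gc_ <- (dz * model$w) * ep
  gp_ <- (dz * model$w) * ec
  idx <- c(center, partner) + 1L
  g <- rowsum(rbind(gc_, gp_), idx)
  dE <- matrix(0, nrow(model$E), ncol(model$E))
  dE[as.integer(rownames(g)), ] <- g
  list(loss = loss, dE = dE, dw = dw, db = db)
}

#' Train codon-switch embeddings by skip-gram classification
#'
#' Minimizes the binary cross-entropy of sigmoid(w * (e_center . e_partner)
#' + b) over the tuple set with the ADAM optimizer (step 1e-3, beta1 0.9,
#' beta2 0.999), shuffled mini-batches, for a fixed number of epochs.
#'
#' @param tuples data.frame from [make_tuples()]/[generate_tuples()]
#' @param L embedding length (default 300)
#' @param epochs training epochs (default 200)
#' @param batch_size mini-batch size
#' @param lr ADAM step size
#' @param seed seed for initialization and shuffling
#' @param chromosome_tag tag stored on the result
#' @param dict dictionary whose ordering fingerprint is stored on the result
#' @return a `crcs_embedding`; the per-epoch training loss is attached as
#'   attribute `loss`
#' @export
train_embeddings <- function(tuples, L = 300L, epochs = 200L,
                             batch_size = 1024L, lr = 1e-3, seed = 1L,
                             chromosome_tag = "NA", dict = NULL) {
  if (nrow(tuples) == 0L)
    crcs_stop("no tuples to train on", "crcs_empty_input")
  model <- init_embedding_model(L = L, seed = seed)
  opt <- adam_init(list(E = model$E, w = model$w, b = model$b), lr = lr)
  losses <- numeric(epochs)
  n <- nrow(tuples)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, n)]
      g <- sgns_loss_and_grad(model, tuples$center[rows],
                              tuples$partner[rows], tuples$label[rows])
      tot <- tot + g$loss * length(rows)
      upd <- adam_step(opt, list(E = g$dE, w = g$dw, b = g$db))
      opt <- upd$opt
      model$E <- model$E - upd$delta$E
      model$w <- model$w - upd$delta$w
      model$b <- model$b - upd$delta$b
    }
    losses[ep] <- tot / n
  }
  out <- crcs_embedding(model$E, chromosome_tag = chromosome_tag,
                        dict_fingerprint = if (!is.null(dict))
                          dict_fingerprint(dict) else NA_character_)
  attr(out, "loss") <- losses
  attr(out, "head") <- list(w = model$w, b = model$b)
  out
}
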