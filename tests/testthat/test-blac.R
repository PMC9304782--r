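test_that("forward pass yields probabilities for any sequence length", {
  emb <- random_embedding(L = 6, seed = 1)
  m <- build_blac(emb, blac_arch(4, 4, 3, 3), seed = 2)
  p <- predict_blac(m, list(sample(0:639, 10, replace = TRUE),
                            sample(0:639, 500, replace = TRUE)))
  expect_length(p, 2L)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("embedding rows stay frozen through training", {
  pool <- separable_pool(n_per_class = 8, len = 10, seed = 3)
  emb <- random_embedding(L = 6, seed = 4)
  before <- emb$values
  m <- build_blac(emb, blac_arch(3, 3, 3, 3), seed = 5)
  m2 <- blac_fit(m, pool$seqs, pool$labels, epochs = 2, batch_size = 8,
                 seed = 6)
  expect_identical(m2$emb, before)
  expect_false(identical(m2$params, m$params))
})

test_that("padded and unpadded forward passes agree", {
  emb <- random_embedding(L = 6, seed = 7)
  m <- build_blac(emb, blac_arch(4, 4, 3, 3), seed = 8)
  set.seed(9)
  seqs <- list(sample(0:639, 12), sample(0:639, 31), sample(0:639, 7))
  joint <- crcs:::blac_forward_batch(m, seqs, train = FALSE)$p
  solo <- vapply(seqs, function(s)
    crcs:::blac_forward_batch(m, list(s), train = FALSE)$p, numeric(1))
  expect_equal(joint, solo, tolerance = 1e-5)
})

test_that("full-network analytic gradients match finite differences", {
  emb <- random_embedding(L = 5, seed = 10)
  m <- build_blac(emb, blac_arch(3, 3, 3, 3), seed = 11)
  set.seed(12)
  idx <- list(sample(0:639, 6), sample(0:639, 4), sample(0:639, 6))
  y <- c(1, 0, 1)
  fwd <- crcs:::blac_forward_batch(m, idx, train = TRUE)
  g <- crcs:::blac_backward_batch(m, fwd$cache, y)
  loss_at <- function(mm)
    crcs:::blac_loss(crcs:::blac_forward_batch(mm, idx, train = TRUE)$p, y)
  eps <- 1e-5
  for (k in names(m$params)) {
    p <- m$params[[k]]
    for (j in sample(length(p), min(3, length(p)))) {
      m2 <- m; m2$params[[k]][j] <- p[j] + eps
      m3 <- m; m3$params[[k]][j] <- p[j] - eps
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      denom <- max(1e-6, abs(num) + abs(g[[k]][j]))
      expect_lt(abs(num - g[[k]][j]) / denom, 1e-5)
    }
  }
})

test_that("embedding/dictionary fingerprint mismatch is caught", {
  emb <- random_embedding(L = 4, seed = 13)
  emb$dict_fingerprint <- "00000000"
  expect_error(build_blac(emb, blac_arch(3, 3, 3, 3), dict = DICT),
               class = "crcs_validation_error")
})

test_that("gene folds partition evenly, deterministically, disjointly", {
  genes <- paste0("G", 1:8)
  f1 <- assign_gene_folds(genes, k = 4, seed = 1)
  expect_setequal(names(f1), genes)
  expect_true(all(table(f1) == 2L))
  expect_identical(f1, assign_gene_folds(genes, k = 4, seed = 1))
  f2 <- assign_gene_folds(paste0("G", 1:9), k = 4, seed = 2)
  expect_true(max(table(f2)) - min(table(f2)) <= 1L)
  for (k in 1:4)
    expect_length(intersect(names(f2)[f2 == k], names(f2)[f2 != k]), 0L)
  expect_error(assign_gene_folds(c("A", "B"), k = 4),
               class = "crcs_validation_error")
})

test_that("training-set filters apply strict length and gene-count rules", {
  mk <- function(gene, len, i) crcs:::switch_seq(paste0("T", i), gene,
                                                 rep(0L, len), NA, "k")
  seqs <- c(lapply(1:200, function(i) mk("BIG", 30, i)),
            lapply(1:199, function(i) mk("SMALL", 30, 1000 + i)),
            list(mk("BIG", 1500, 9999)))
  out <- filter_training_set(seqs, max_len = 1500, min_gene_variants = 200)
  genes <- vapply(out, function(s) s$gene_symbol, "")
  expect_false(any(lengths(lapply(out, function(s) s$indices)) >= 1500))
  expect_false("SMALL" %in% genes)         # 199 < 200 after length cut
  expect_equal(sum(genes == "BIG"), 200L)  # the length-1500 one dropped
  expect_length(filter_training_set(list()), 0L)
})

test_that("cross-validated training learns separable classes gene-disjointly", {
  pool <- separable_pool(n_per_class = 48, len = 16, n_genes = 8, seed = 14)
  emb <- random_embedding(L = 6, seed = 15)
  cv <- train_blac(pool$seqs, pool$labels, emb, blac_arch(5, 5, 4, 4),
                   folds = 4, epochs = 12, batch_size = 16, lr = 5e-3,
                   seed = 16)
  expect_gt(cv$ap, 0.9)
  # gene-fold hygiene: scoring model never saw the scored gene
  for (f in unique(cv$scores$fold)) {
    va_genes <- unique(cv$scores$gene[cv$scores$fold == f])
    tr_genes <- names(cv$fold_assignment)[cv$fold_assignment != f]
    expect_length(intersect(va_genes, tr_genes), 0L)
  }
  # every sequence scored exactly once
  expect_equal(nrow(cv$scores), length(pool$seqs))
  # training loss decreased on a directly fitted model
  m <- build_blac(emb, blac_arch(5, 5, 4, 4), seed = 17)
  m <- blac_fit(m, pool$seqs, pool$labels, epochs = 6, batch_size = 16,
                lr = 5e-3, seed = 17)
  loss <- attr(m, "loss")
  expect_lt(loss[6], loss[1])
})

test_that("degenerate training inputs are rejected and runs are seeded", {
  pool <- separable_pool(n_per_class = 8, len = 8, seed = 18)
  emb <- random_embedding(L = 4, seed = 19)
  expect_error(blac_fit(build_blac(emb, blac_arch(3, 3, 3, 3)), pool$seqs,
                        rep(1L, length(pool$seqs))),
               class = "crcs_validation_error")
  cv1 <- train_blac(pool$seqs, pool$labels, emb, blac_arch(3, 3, 3, 3),
                    folds = 4, epochs = 2, batch_size = 8, seed = 20,
                    keep_models = FALSE)
  cv2 <- train_blac(pool$seqs, pool$labels, emb, blac_arch(3, 3, 3, 3),
                    folds = 4, epochs = 2, batch_size = 8, seed = 20,
                    keep_models = FALSE)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$scores$score, cv2$scores$score)
  expect_error(fake_split_control(pool$seqs[1:10], emb,
                                  blac_arch(3, 3, 3, 3), folds = 4),
               class = "crcs_validation_error")
})
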