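test_that("switch frequencies count occurrences and normalize", {
  f <- switch_frequencies(list(c(5L, 5L, 9L)))
  expect_equal(f[6], 2 / 3)
  expect_equal(f[10], 1 / 3)
  expect_equal(sum(f), 1)
  expect_equal(f[100], 0)
  expect_error(switch_frequencies(list()), class = "crcs_empty_input")
})

test_that("keep probability follows the subsampling formula", {
  expect_equal(keep_probability(0.001, 0.001), 1)           # sqrt(2) > 1
  expect_equal(keep_probability(0.1, 0.001), sqrt(101) * 0.01,
               tolerance = 1e-12)
  expect_equal(keep_probability(0.1, 0.001), 0.100499, tolerance = 1e-5)
  expect_equal(keep_probability(0, 0.001), 1)               # limit
  grid <- seq(0.002, 0.9, by = 0.002)
  expect_true(all(diff(keep_probability(grid)) < 0))        # monotone
  expect_error(keep_probability(-0.1), class = "crcs_validation_error")
})

test_that("center selection is seeded and matches its binomial rate", {
  seq_idx <- rep(3L, 4000L)
  freqs <- numeric(640); freqs[4] <- 0.1
  sel1 <- select_centers(seq_idx, freqs, seed = 5)
  sel2 <- select_centers(seq_idx, freqs, seed = 5)
  expect_identical(sel1, sel2)
  p <- keep_probability(0.1)
  se <- sqrt(p * (1 - p) / 4000)
  expect_lt(abs(length(sel1) / 4000 - p), 3 * se)
  # frequencies at or below epsilon select everything
  lowf <- numeric(640); lowf[4] <- 0.0005
  expect_length(select_centers(seq_idx[1:50], lowf, seed = 1), 50L)
})

test_that("tuple construction matches the windowed counts and an oracle", {
  s <- 0:19
  tp_mid <- make_tuples(s, centers = 10L, ws = 3, nsr = 0.2, seed = 1)
  expect_equal(sum(tp_mid$label == 1), 6L)   # 2 * ws interior positives
  expect_equal(sum(tp_mid$label == 0), 2L)   # ceil(7 * 0.2)
  tp_end <- make_tuples(s, centers = 1L, ws = 3, nsr = 0.2, seed = 1)
  expect_equal(sum(tp_end$label == 1), 3L)   # one-sided corner window

  # brute-force window enumeration oracle over random sequences
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    idx <- sample(0:639, n, replace = TRUE)
    centers <- sort(sample(n, sample(1:n, 1)))
    ws <- sample(1:4, 1)
    tp <- make_tuples(idx, centers, ws = ws, nsr = 0.2, seed = rep)
    pos <- tp[tp$label == 1, ]
    n_pos_expected <- 0L
    for (c0 in centers) {
      ctx <- setdiff(seq(max(1, c0 - ws), min(n, c0 + ws)), c0)
      n_pos_expected <- n_pos_expected + length(ctx)
      # every in-window partner of this center appears (as a multiset)
      expect_true(all(idx[ctx] %in% pos$partner[pos$center == idx[c0]]))
    }
    expect_equal(nrow(pos), n_pos_expected)
    expect_equal(sum(tp$label == 0),
                 length(centers) * ceiling((2 * ws + 1) * 0.2))
    expect_true(all(tp$partner >= 0 & tp$partner <= 639))
  }
})

test_that("embedding network has the documented parameter count", {
  expect_equal(n_trainable(init_embedding_model()), 192002L)
  expect_equal(n_trainable(init_embedding_model(L = 10)), 6402L)
})

test_that("SGNS gradient matches finite differences", {
  model <- init_embedding_model(L = 4, seed = 2)
  center <- c(3L, 100L, 3L)
  partner <- c(10L, 20L, 30L)
  label <- c(1, 0, 1)
  g <- crcs:::sgns_loss_and_grad(model, center, partner, label)
  eps <- 1e-6
  num_grad <- function(set, get) {
    m2 <- set(eps); m3 <- set(-eps)
    (crcs:::sgns_loss_and_grad(m2, center, partner, label)$loss -
       crcs:::sgns_loss_and_grad(m3, center, partner, label)$loss) / (2 * eps)
  }
  for (i in c(4L, 11L, 101L)) {
    for (j in 1:4) {
      num <- num_grad(function(d) {
        m <- model; m$E[i, j] <- m$E[i, j] + d; m
      })
      expect_equal(g$dE[i, j], num, tolerance = 1e-5)
    }
  }
  numw <- num_grad(function(d) { m <- model; m$w <- m$w + d; m })
  expect_equal(g$dw, numw, tolerance = 1e-5)
  numb <- num_grad(function(d) { m <- model; m$b <- m$b + d; m })
  expect_equal(g$db, numb, tolerance = 1e-5)
})

test_that("embedding training descends and is deterministic", {
  # separable toy: pairs (1,2) positive, (1,500) negative
  tp <- data.frame(center = rep(c(1L, 1L), each = 40),
                   partner = rep(c(2L, 500L), each = 40),
                   label = rep(c(1L, 0L), each = 40))
  e1 <- train_embeddings(tp, L = 6, epochs = 5, seed = 4)
  loss <- attr(e1, "loss")
  expect_lt(loss[5], loss[1])
  e2 <- train_embeddings(tp, L = 6, epochs = 5, seed = 4)
  expect_identical(e1$values, e2$values)
  expect_error(train_embeddings(tp[0, ], L = 6), class = "crcs_empty_input")
})

test_that("co-occurring switches embed closer than never-co-occurring", {
  # switch a always sits next to b; c exists in other sequences only
  a <- 7L; b <- 8L; cc <- 200L
  corpus <- c(replicate(30, c(a, b, a, b, a, b), simplify = FALSE),
              replicate(30, rep(cc, 6), simplify = FALSE))
  tp <- generate_tuples(corpus, ws = 1, nsr = 0.2, seed = 6)
  emb <- train_embeddings(tp, L = 8, epochs = 60, seed = 7)
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  E <- emb$values
  expect_gt(cosine(E[a + 1, ], E[b + 1, ]), cosine(E[a + 1, ], E[cc + 1, ]))
})
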