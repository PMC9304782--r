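# Minimal neural-network numerics used by the embedding trainer and BLAC:
# ADAM over named lists of arrays, a masked LSTM (both directions), batch
# normalization over valid (non-padded) positions, additive attention and a
# dense sigmoid head. Everything is plain batched matrix algebra so gradients
# can be verified against finite differences in the test suite.

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  zeros <- lapply(params, function(p) p * 0)
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = zeros, v = zeros)
}

adam_step <- function(opt, grads) {
  opt$t <- opt$t + 1L
  delta <- vector("list", length(grads))
  names(delta) <- names(grads)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (k in names(grads)) {
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * grads[[k]]
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * grads[[k]]^2
    delta[[k]] <- opt$lr * (opt$m[[k]] / bc1) /
      (sqrt(opt$v[[k]] / bc2) + opt$eps)
  }
  list(opt = opt, delta = delta)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

lstm_init <- function(n_in, n_units) {
  b <- rep(0, 4 * n_units)
  b[(n_units + 1):(2 * n_units)] <- 1  # forget-gate bias starts open
  list(Wx = glorot(n_in, 4 * n_units), Wh = glorot(n_units, 4 * n_units),
       b = b)
}

# X: list over time of B x n_in matrices; mask: B x T 0/1.
# Padded steps carry state through unchanged, so outputs are
# padding-invariant. reverse = TRUE runs from the last step backwards.
lstm_forward <- function(X, mask, W, reverse = FALSE) {
  T_ <- length(X); B <- nrow(X[[1]]); u <- nrow(W$Wh)
  order_t <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  h <- matrix(0, B, u); cc <- matrix(0, B, u)
  H <- vector("list", T_)
  cache <- vector("list", T_)
  for (t in order_t) {
    m <- mask[, t]
    A <- X[[t]] %*% W$Wx + h %*% W$Wh +
      matrix(W$b, B, 4 * u, byrow = TRUE)
    i_ <- sigmoid(A[, 1:u, drop = FALSE])
    f_ <- sigmoid(A[, (u + 1):(2 * u), drop = FALSE])
    g_ <- tanh(A[, (2 * u + 1):(3 * u), drop = FALSE])
    o_ <- sigmoid(A[, (3 * u + 1):(4 * u), drop = FALSE])
    c_new <- f_ * cc + i_ * g_
    h_new <- o_ * tanh(c_new)
    c_next <- m * c_new + (1 - m) * cc
    h_next <- m * h_new + (1 - m) * h
    cache[[t]] <- list(x = X[[t]], h_prev = h, c_prev = cc, i = i_, f = f_,
                       g = g_, o = o_, c_new = c_new, m = m)
    h <- h_next; cc <- c_next
    H[[t]] <- h
  }
  list(H = H, cache = cache, W = W, reverse = reverse)
}

lstm_backward <- function(dH, fwd) {
  W <- fwd$W; cache <- fwd$cache
  T_ <- length(dH); B <- nrow(dH[[1]]); u <- nrow(W$Wh)
  order_t <- if (fwd$reverse) seq_len(T_) else rev(seq_len(T_))
  dWx <- W$Wx * 0; dWh <- W$Wh * 0; db <- W$b * 0
  dh_carry <- matrix(0, B, u); dc_carry <- matrix(0, B, u)
  dX <- vector("list", T_)
  for (t in order_t) {
    cc <- cache[[t]]
    m <- cc$m
    dh_tot <- dH[[t]] + dh_carry
    dc_tot <- dc_carry
    dh_new <- dh_tot * m
    dh_prev <- dh_tot * (1 - m)
    tc <- tanh(cc$c_new)
    dc_new <- dc_tot * m + dh_new * cc$o * (1 - tc^2)
    dc_prev <- dc_tot * (1 - m) + dc_new * cc$f
    do_ <- dh_new * tc
    di <- dc_new * cc$g
    dg <- dc_new * cc$i
    df <- dc_new * cc$c_prev
    dA <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o))
    dX[[t]] <- dA %*% t(W$Wx)
    dh_prev <- dh_prev + dA %*% t(W$Wh)
    dWx <- dWx + t(cc$x) %*% dA
    dWh <- dWh + t(cc$h_prev) %*% dA
    db <- db + colSums(dA)
    dh_carry <- dh_prev; dc_carry <- dc_prev
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

bn_init <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d),
       run_mean = rep(0, d), run_var = rep(1, d))
}

# X: list over time of B x d; statistics over valid (mask == 1) positions
# only. In training mode returns updated running stats (momentum 0.99).
bn_forward <- function(X, mask, P, train = TRUE, momentum = 0.99,
                       eps = 1e-5) {
  T_ <- length(X); B <- nrow(X[[1]]); d <- ncol(X[[1]])
  flat <- do.call(rbind, X)                       # (T*B) x d, time-major
  valid <- as.vector(mask) != 0  # column t of mask aligns with time-block t
  if (train) {
    mu <- colMeans(flat[valid, , drop = FALSE])
    va <- colMeans(sweep(flat[valid, , drop = FALSE], 2, mu)^2)
  } else {
    mu <- P$run_mean; va <- P$run_var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(flat, 2, mu), 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, P$gamma, `*`), 2, P$beta, `+`)
  Y <- lapply(seq_len(T_), function(t) y[((t - 1) * B + 1):(t * B), ,
                                         drop = FALSE])
  P_new <- P
  if (train) {
    P_new$run_mean <- momentum * P$run_mean + (1 - momentum) * mu
    P_new$run_var <- momentum * P$run_var + (1 - momentum) * va
  }
  list(Y = Y, P = P_new,
       cache = list(xhat = xhat, inv = inv, valid = valid, B = B, T_ = T_,
                    gamma = P$gamma))
}

bn_backward <- function(dY, cache) {
  T_ <- cache$T_; B <- cache$B
  dy <- do.call(rbind, dY)
  valid <- cache$valid
  N <- sum(valid)
  dxhat <- sweep(dy, 2, cache$gamma, `*`)
  dxv <- dxhat[valid, , drop = FALSE]
  xhv <- cache$xhat[valid, , drop = FALSE]
  s1 <- colSums(dxv)
  s2 <- colSums(dxv * xhv)
  dx <- matrix(0, nrow(dy), ncol(dy))
  dx[valid, ] <- sweep(
    dxv * N - matrix(s1, N, length(s1), byrow = TRUE) -
      xhv * matrix(s2, N, length(s2), byrow = TRUE),
    2, cache$inv / N, `*`)
  dgamma <- colSums(dy[valid, , drop = FALSE] * xhv)
  dbeta <- colSums(dy[valid, , drop = FALSE])
  dX <- lapply(seq_len(T_), function(t) dx[((t - 1) * B + 1):(t * B), ,
                                           drop = FALSE])
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

attn_init <- function(d_in, d_attn) {
  list(Wa = glorot(d_in, d_attn), ba = rep(0, d_attn),
       v = stats::runif(d_attn, -0.1, 0.1))
}

# Additive attention: score_t = v' tanh(Wa x_t + ba), masked softmax over
# time, context = sum_t alpha_t x_t.
attn_forward <- function(X, mask, P) {
  T_ <- length(X); B <- nrow(X[[1]])
  U <- vector("list", T_)
  S <- matrix(-Inf, B, T_)
  for (t in seq_len(T_)) {
    u <- tanh(X[[t]] %*% P$Wa + matrix(P$ba, B, length(P$ba), byrow = TRUE))
    U[[t]] <- u
    S[, t] <- as.vector(u %*% P$v)
  }
  S[mask == 0] <- -Inf
  mx <- apply(S, 1, max)
  E <- exp(S - mx)
  E[mask == 0] <- 0
  alpha <- E / rowSums(E)
  ctx <- matrix(0, B, ncol(X[[1]]))
  for (t in seq_len(T_)) ctx <- ctx + alpha[, t] * X[[t]]
  list(context = ctx, alpha = alpha, cache = list(X = X, U = U, alpha = alpha,
                                                  mask = mask, P = P))
}

attn_backward <- function(dctx, cache) {
  X <- cache$X; U <- cache$U; alpha <- cache$alpha; P <- cache$P
  T_ <- length(X); B <- nrow(dctx)
  dX <- vector("list", T_)
  dalpha <- matrix(0, B, T_)
  for (t in seq_len(T_)) {
    dX[[t]] <- alpha[, t] * dctx
    dalpha[, t] <- rowSums(dctx * X[[t]])
  }
  dS <- alpha * (dalpha - rowSums(alpha * dalpha))
  dS[cache$mask == 0] <- 0
  dWa <- P$Wa * 0; dba <- P$ba * 0; dv <- P$v * 0
  for (t in seq_len(T_)) {
    ds <- dS[, t]
    dv <- dv + as.vector(t(U[[t]]) %*% ds)
    du <- outer(ds, P$v)
    dpre <- du * (1 - U[[t]]^2)
    dWa <- dWa + t(X[[t]]) %*% dpre
    dba <- dba + colSums(dpre)
    dX[[t]] <- dX[[t]] + dpre %*% t(P$Wa)
  }
  list(dX = dX, dWa = dWa, dba = dba, dv = dv)
}
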