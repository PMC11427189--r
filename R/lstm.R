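# Batched LSTM with explicit backpropagation through time, plus the
# actor/critic heads and an Adam optimizer. The observation matrix is
# consumed as a length-(2N+1) sequence of (N+1)-vectors. The training hot
# path runs through the compiled core in src/lstm.cpp; the plain-R
# implementation below is retained as the reference oracle the compiled
# route is tested against.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.init_mat <- function(nr, nc, r) matrix(stats::runif(nr * nc, -r, r), nr, nc)

# LSTM parameter block: input weights Wx (d x 4h), recurrent weights
# Wh (h x 4h), bias b (4h). Gate order: input, forget, cell, output; the
# forget-gate bias starts at +1.
lstm_init <- function(d, h) {
  r <- 1 / sqrt(h)
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1
  list(Wx = .init_mat(d, 4 * h, r), Wh = .init_mat(h, 4 * h, r), b = b)
}

# X: B x T x d array. Returns final hidden state (B x h) and the cache
# needed for backward.  The input projection for all timesteps is done in
# one matrix product; the sigmoid gates (input/forget/output) share one
# exp() call per step.
lstm_forward <- function(p, X) {
  B <- dim(X)[1]; TT <- dim(X)[2]; d <- dim(X)[3]
  h <- nrow(p$Wh)
  gi <- 2 * h + seq_len(h)
  sg <- c(seq_len(2 * h), 3 * h + seq_len(h))   # i, f, o gate columns
  Xf <- matrix(X, B * TT, d)                    # (B*T) x d, t-major blocks
  Zx <- Xf %*% p$Wx
  H <- matrix(0, B, h); C <- matrix(0, B, h)
  bmat <- rep(p$b, each = B)
  steps <- vector("list", TT)
  rows <- seq_len(B)
  for (t in seq_len(TT)) {
    z <- Zx[rows + (t - 1L) * B, , drop = FALSE] + H %*% p$Wh + bmat
    s <- 1 / (1 + exp(-z[, sg, drop = FALSE]))
    i <- s[, seq_len(h), drop = FALSE]
    f <- s[, h + seq_len(h), drop = FALSE]
    o <- s[, 2 * h + seq_len(h), drop = FALSE]
    g <- tanh(z[, gi, drop = FALSE])
    Cprev <- C
    C <- f * Cprev + i * g
    tC <- tanh(C)
    steps[[t]] <- list(Hprev = H, Cprev = Cprev,
                       i = i, f = f, g = g, o = o, tC = tC)
    H <- o * tC
  }
  list(H = H, steps = steps, Xf = Xf,
       dims = c(B = B, TT = TT, d = d, h = h))
}

# Backpropagate dH (gradient at the final hidden state, B x h) through
# time; returns parameter gradients.
lstm_backward <- function(p, fwd, dH) {
  dm <- fwd$dims
  B <- dm[["B"]]; TT <- dm[["TT"]]; h <- dm[["h"]]
  ii <- seq_len(h); fi <- h + ii; gi <- 2 * h + ii; oi <- 3 * h + ii
  dWh <- 0 * p$Wh; db <- 0 * p$b
  dC <- matrix(0, B, h)
  dz <- matrix(0, B, 4 * h)
  dZx <- matrix(0, B * TT, 4 * h)
  tWh <- t(p$Wh)
  rows <- seq_len(B)
  for (t in rev(seq_len(TT))) {
    s <- fwd$steps[[t]]
    dO <- dH * s$tC
    dC <- dC + dH * s$o * (1 - s$tC^2)
    dz[, ii] <- (dC * s$g) * s$i * (1 - s$i)
    dz[, fi] <- (dC * s$Cprev) * s$f * (1 - s$f)
    dz[, gi] <- (dC * s$i) * (1 - s$g^2)
    dz[, oi] <- dO * s$o * (1 - s$o)
    dZx[rows + (t - 1L) * B, ] <- dz
    dWh <- dWh + crossprod(s$Hprev, dz)
    db <- db + colSums(dz)
    dH <- dz %*% tWh
    dC <- dC * s$f
  }
  list(Wx = crossprod(fwd$Xf, dZx), Wh = dWh, b = db)
}

# ---- actor: LSTM encoder -> bounded coefficient head --------------------

actor_init <- function(d, h, N) {
  p <- lstm_init(d, h)
  r <- 1 / sqrt(h)
  p$Wa <- .init_mat(h, N, r)
  p$ba <- numeric(N)
  p
}

actor_forward <- function(p, X, limit) {
  B <- dim(X)[1]; TT <- dim(X)[2]; d <- dim(X)[3]
  Xf <- matrix(X, B * TT, d)
  H <- lstm_H_cpp(p$Wx, p$Wh, p$b, Xf, B, TT)
  u <- H %*% p$Wa + rep(p$ba, each = B)
  th <- tanh(u)
  list(A = limit * th, H = H, Xf = Xf, B = B, TT = TT, th = th)
}

actor_backward <- function(p, cache, dA, limit) {
  du <- dA * limit * (1 - cache$th^2)
  g <- lstm_grad_cpp(p$Wx, p$Wh, p$b, cache$Xf, cache$B, cache$TT,
                     du %*% t(p$Wa))
  g$b <- drop(g$b)
  g$Wa <- crossprod(cache$H, du)
  g$ba <- colSums(du)
  g
}

# ---- critic: LSTM encoder + action -> scalar value ----------------------

critic_init <- function(d, h, N, h2) {
  p <- lstm_init(d, h)
  r1 <- 1 / sqrt(h + N)
  p$W1 <- .init_mat(h + N, h2, r1)
  p$b1 <- numeric(h2)
  p$w2 <- .init_mat(h2, 1, 1 / sqrt(h2))
  p$b2 <- 0
  p
}

# A is B x N (actions scaled to [-1, 1] by the caller).
critic_forward <- function(p, X, A) {
  B <- dim(X)[1]; TT <- dim(X)[2]; d <- dim(X)[3]
  Xf <- matrix(X, B * TT, d)
  H <- lstm_H_cpp(p$Wx, p$Wh, p$b, Xf, B, TT)
  z <- cbind(H, A)
  u <- z %*% p$W1 + rep(p$b1, each = B)
  relu <- pmax(u, 0)
  q <- drop(relu %*% p$w2) + p$b2
  list(q = q, H = H, Xf = Xf, B = B, TT = TT, z = z, u = u, relu = relu)
}

# dq: gradient w.r.t. the scalar outputs (length B). When want_dA, also
# returns the gradient w.r.t. the (scaled) action inputs.
critic_backward <- function(p, cache, dq, want_dA = FALSE) {
  B <- length(dq)
  drelu <- matrix(dq, B, 1) %*% t(p$w2)
  du <- drelu * (cache$u > 0)
  dz <- du %*% t(p$W1)
  h <- ncol(cache$H)
  g <- lstm_grad_cpp(p$Wx, p$Wh, p$b, cache$Xf, cache$B, cache$TT,
                     dz[, seq_len(h), drop = FALSE])
  g$b <- drop(g$b)
  g$W1 <- crossprod(cache$z, du)
  g$b1 <- colSums(du)
  g$w2 <- crossprod(cache$relu, matrix(dq, B, 1))
  g$b2 <- sum(dq)
  if (want_dA) attr(g, "dA") <- dz[, -seq_len(h), drop = FALSE]
  g
}

# Gradient of the critic output w.r.t. its (scaled) action inputs only.
# The action joins after the recurrent encoder, so this needs no
# backpropagation through time - just the head.
critic_dA <- function(p, cache, dq) {
  B <- length(dq)
  drelu <- matrix(dq, B, 1) %*% t(p$w2)
  du <- drelu * (cache$u > 0)
  dz <- du %*% t(p$W1)
  dz[, -seq_len(ncol(cache$H)), drop = FALSE]
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) 0 * p),
       v = lapply(params, function(p) 0 * p), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
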