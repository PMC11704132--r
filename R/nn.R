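# Minimal neural-network primitives: explicit forward/backward passes over
# named parameter lists, and an Adam optimizer. Gradients are hand-derived
# and verified against finite differences in the test suite.

rmat <- function(n, m, sd = 0.02) matrix(rnorm(n * m, 0, sd), n, m)

softmax_rows <- function(S) {
  S <- S - max(S) # scalar shift suffices for numerical stability here
  E <- exp(S)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# "quick" GELU: x * sigmoid(1.702 x) — the standard cheap approximation.
gelu_fwd <- function(X) X * sigmoid(1.702 * X)
gelu_bwd <- function(X, dY) {
  s <- sigmoid(1.702 * X)
  dY * (s + 1.702 * X * s * (1 - s))
}

silu_fwd <- function(X) X * sigmoid(X)
silu_bwd <- function(X, dY) {
  s <- sigmoid(X)
  dY * (s * (1 + X * (1 - s)))
}

# Row-wise layer normalization with learned gain/bias over the feature axis.
ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  s <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / s
  list(Y = sweep(xhat, 2, g, `*`) + matrix(b, nrow(X), length(b), byrow = TRUE),
       xhat = xhat, s = s)
}

ln_bwd <- function(dY, g, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) / cache$s
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# Single-head scaled dot-product attention. Queries come from Xq (P x d),
# keys/values from Ctx (L x d); self-attention passes Ctx = Xq.
attn_fwd <- function(Xq, Ctx, Wq, Wk, Wv, Wo) {
  d <- ncol(Wq)
  Q <- Xq %*% Wq
  K <- Ctx %*% Wk
  V <- Ctx %*% Wv
  A <- softmax_rows(tcrossprod(Q, K) / sqrt(d))
  AV <- A %*% V
  list(O = AV %*% Wo, Q = Q, K = K, V = V, A = A, AV = AV, Xq = Xq, Ctx = Ctx)
}

attn_bwd <- function(dO, cache, Wq, Wk, Wv, Wo) {
  d <- ncol(Wq)
  dWo <- crossprod(cache$AV, dO)
  dAV <- tcrossprod(dO, Wo)
  dA <- tcrossprod(dAV, cache$V)
  dV <- crossprod(cache$A, dAV)
  dS <- cache$A * (dA - rowSums(dA * cache$A))
  dQ <- dS %*% cache$K / sqrt(d)
  dK <- crossprod(dS, cache$Q) / sqrt(d)
  list(dXq = tcrossprod(dQ, Wq),
       dCtx = tcrossprod(dK, Wk) + tcrossprod(dV, Wv),
       dWq = crossprod(cache$Xq, dQ), dWk = crossprod(cache$Ctx, dK),
       dWv = crossprod(cache$Ctx, dV), dWo = dWo)
}

# Adam with optional decoupled weight decay; params/grads are flat named
# lists of numeric arrays with matching names.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       step = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

grad_zero_like <- function(params) lapply(params, function(p) p * 0)

grad_accum <- function(acc, g) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

grad_scale <- function(g, s) lapply(g, function(x) x * s)

# Sinusoidal features of a (possibly fractional) time index.
time_features <- function(t, dim = 32) {
  half <- dim / 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / half)
  c(sin(t * freqs), cos(t * freqs))
}
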