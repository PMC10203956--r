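# Shared numerical machinery: parameter init, Adam, the MLP decision head.

glorot_init <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# MLP head: flattened latent row-vectors V (batch x n_max*d) -> 2 logits
head_forward <- function(V, params) {
  A1p <- sweep(V %*% params$U1, 2L, params$b1, `+`)
  A1 <- relu(A1p)
  logits <- sweep(A1 %*% params$U2, 2L, params$b2, `+`)
  list(A1p = A1p, A1 = A1, logits = logits, P = softmax_rows(logits))
}

# returns head-parameter gradients plus dL/dV; dlogits already includes the
# 1/batch factor
head_backward <- function(V, cache, dlogits, params) {
  gU2 <- crossprod(cache$A1, dlogits)
  gb2 <- colSums(dlogits)
  dA1 <- (dlogits %*% t(params$U2)) * (cache$A1p > 0)
  gU1 <- crossprod(V, dA1)
  gb1 <- colSums(dA1)
  dV <- dA1 %*% t(params$U1)
  list(gU1 = gU1, gb1 = gb1, gU2 = gU2, gb2 = gb2, dV = dV)
}

cross_entropy <- function(P, y) {
  eps <- 1e-12
  -mean(log(pmax(P[cbind(seq_along(y), y)], eps)))
}

# seeded stratified shuffle-free batching: plain shuffled index batches
epoch_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}
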