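# Shared fixtures built in code.

# linearly separable toy set: the blocker class carries an N/O/S
# substituent on benzene, the non-blocker class a carbon/halogen one
toy_separable <- function() {
  data.frame(
    smiles = c(
      "c1ccc(N)cc1", "c1ccc(O)cc1", "c1ccc(S)cc1", "c1ccc(NC)cc1",
      "c1ccc(OC)cc1", "c1ccc(SC)cc1", "c1ccc(N(C)C)cc1", "c1ccc(CN)cc1",
      "c1ccc(CO)cc1", "c1ccc(C#N)cc1",
      "c1ccc(C)cc1", "c1ccc(CC)cc1", "c1ccc(CCC)cc1", "c1ccc(C(C)C)cc1",
      "c1ccc(Cl)cc1", "c1ccc(F)cc1", "c1ccc(Br)cc1", "c1ccc(C=C)cc1",
      "c1ccc(C(F)(F)F)cc1", "c1ccc(CCl)cc1"
    ),
    label = rep(c("blocker", "non_blocker"), each = 10L),
    stringsAsFactors = FALSE
  )
}

# random symmetric binary zero-diagonal adjacency on n nodes
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(stats::runif(sum(up)) < p)
  A + t(A)
}

# random subgraph tensor: T slices, each a random symmetric mask of A
random_tensor <- function(n, T_, p = 0.4) {
  A <- random_adjacency(n, p)
  lapply(seq_len(T_), function(t) {
    mask <- matrix(0, n, n)
    up <- upper.tri(mask)
    mask[up] <- as.numeric(stats::runif(sum(up)) < 0.7)
    A * (mask + t(mask))
  })
}

random_prob_vector <- function(T_) {
  w <- stats::runif(T_)
  w / sum(w)
}

# brute-force oracles (independent of the package's vectorized code paths)
oracle_meta_path <- function(G, w) {
  n <- nrow(G[[1]])
  Q <- matrix(0, n, n)
  for (i in seq_along(G)) {
    for (a in seq_len(n)) {
      for (b in seq_len(n)) Q[a, b] <- Q[a, b] + w[i] * G[[i]][a, b]
    }
  }
  Q
}

oracle_matmul <- function(A, B) {
  n <- nrow(A); m <- ncol(B); k <- ncol(A)
  C <- matrix(0, n, m)
  for (a in seq_len(n)) {
    for (b in seq_len(m)) {
      s <- 0
      for (c in seq_len(k)) s <- s + A[a, c] * B[c, b]
      C[a, b] <- s
    }
  }
  C
}

oracle_normalize_propagator <- function(Qp) {
  n <- nrow(Qp)
  S <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) S[a, b] <- (Qp[a, b] + Qp[b, a]) / 2
  }
  for (a in seq_len(n)) S[a, a] <- S[a, a] + 1
  d <- numeric(n)
  for (a in seq_len(n)) d[a] <- sum(S[a, ])
  out <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) out[a, b] <- S[a, b] / sqrt(d[a] * d[b])
  }
  out
}

# pairwise-concordance AUC by exhaustive pair enumeration
oracle_auc <- function(y, s, positive = "blocker") {
  pos <- which(y == positive)
  neg <- which(y != positive)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
  }
  tot / (length(pos) * length(neg))
}
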