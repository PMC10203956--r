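# Core meta-path / graph-convolution algebra of the subgraph transformer.
#
# Conventions: a subgraph tensor M holds T symmetric, binary, zero-diagonal
# slices G_i <= A. A meta-path Q is a convex combination sum_i w_i G_i; the
# multi-head product Q_p = Q_1 ... Q_n composes the per-head meta-paths into
# n-hop relations. The propagator used by the convolution is the
# symmetrically normalized D^(-1/2) (S + I) D^(-1/2) with S the symmetrized
# Q_p; products of symmetric matrices need not be symmetric, and molecular
# graphs are undirected, hence the explicit symmetrization.

tensor_slices <- function(M) {
  if (inherits(M, "gstn_tensor")) M <- M$M
  if (is.list(M)) return(M)
  stopifnot(is.array(M), length(dim(M)) == 3L)
  lapply(seq_len(dim(M)[1]), function(t) M[t, , ])
}

#' Meta-path matrix from weighted subgraphs
#'
#' Computes `Q = sum_i w_i G_i`, the attention-weighted combination of the
#' subgraph slices.
#'
#' @param M a `gstn_tensor`, a 3-D array `T x n x n`, or a list of `T`
#'   matrices.
#' @param w nonnegative weight vector of length `T` (normally a
#'   probability vector).
#' @return an `n x n` matrix.
#' @export
meta_path <- function(M, w) {
  G <- tensor_slices(M)
  if (length(w) != length(G)) {
    stop("length(w) = ", length(w), " does not match T = ", length(G),
         call. = FALSE)
  }
  if (any(w < 0)) stop("meta-path weights must be nonnegative", call. = FALSE)
  Q <- w[1] * G[[1]]
  for (i in seq_along(G)[-1]) Q <- Q + w[i] * G[[i]]
  Q
}

#' Multi-head meta-path product
#'
#' Computes the ordered matrix product `Q_p = Q_1 Q_2 ... Q_n` of the
#' per-head meta-paths, where head `k` uses the normalized weight vector in
#' row `k` of `w`.
#'
#' @param M as in [meta_path()].
#' @param w numeric matrix `n_heads x T` of per-head weights (each row
#'   nonnegative; normally summing to 1), or a vector for a single head.
#' @return an `n x n` matrix; with one head this is just `Q_1`.
#' @export
multi_head_meta_path <- function(M, w) {
  if (is.vector(w)) w <- matrix(w, nrow = 1L)
  Qk <- lapply(seq_len(nrow(w)), function(k) meta_path(M, w[k, ]))
  Reduce(`%*%`, Qk)
}

#' Symmetrically normalized propagator
#'
#' Given a nonnegative meta-path product `Q_p`, forms
#' `S = (Q_p + Q_p') / 2`, adds the identity self-loop, and returns
#' `D^(-1/2) (S + I) D^(-1/2)` where `D` is the diagonal degree matrix of
#' `S + I`. All degrees are at least 1, so the normalization is defined
#' even for fully padded (isolated) nodes.
#'
#' @param Q_p square matrix with nonnegative entries.
#' @return the normalized propagator matrix.
#' @export
normalize_propagator <- function(Q_p) {
  if (any(Q_p < 0)) {
    stop("propagator input has negative entries; meta-path weights must be ",
         "nonnegative", call. = FALSE)
  }
  S <- (Q_p + t(Q_p)) / 2
  diag(S) <- diag(S) + 1
  d <- rowSums(S)
  dm <- 1 / sqrt(d)
  S * outer(dm, dm)
}

.activations <- list(
  relu = list(f = function(x) pmax(x, 0), grad = function(pre) (pre > 0) * 1),
  identity = list(f = function(x) x, grad = function(pre) array(1, dim(pre)))
)

#' Graph convolution stack
#'
#' Applies `L` message-passing layers
#' `X <- act(P %*% X %*% W[[l]])` where `P` is the normalized propagator of
#' `Q_p`, computed once and reused across all layers. `weights = list()`
#' returns `X` unchanged.
#'
#' @param X node-feature matrix (`n x D_in`).
#' @param Q_p meta-path product matrix.
#' @param weights list of per-layer transform matrices with conformable
#'   shapes (`D_in -> D_1 -> ... -> D_L`).
#' @param activation `"relu"` (default) or `"identity"`.
#' @return the final `n x D_L` feature matrix.
#' @export
graph_convolution <- function(X, Q_p, weights = list(),
                              activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  act <- .activations[[activation]]$f
  if (!length(weights)) return(X)
  P <- normalize_propagator(Q_p)
  for (W in weights) {
    if (ncol(X) != nrow(W)) {
      stop("layer shape mismatch: features ", ncol(X), " vs weight rows ",
           nrow(W), call. = FALSE)
    }
    X <- act(P %*% (X %*% W))
  }
  X
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

relu <- function(x) pmax(x, 0)

# row-major ("row-prime") flatten of an n x d latent block into a vector of
# length n_max * d, padded with zeros beyond the real atoms
flatten_latent <- function(Z, n_max) {
  d <- ncol(Z)
  v <- numeric(n_max * d)
  v[seq_len(nrow(Z) * d)] <- as.vector(t(Z))
  v
}
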