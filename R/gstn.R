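# The graph subgraph transformer network: fitting, prediction, methods.

gstn_config <- function(kinds, n_heads = 2L, n_layers = 2L, hidden = 128L,
                        d_latent = 64L, epochs = 100L, lr = 1e-3,
                        batch_size = 64L, n_max = 45L, seed = 1L) {
  list(kinds = kinds, n_heads = as.integer(n_heads),
       n_layers = as.integer(n_layers), hidden = as.integer(hidden),
       d_latent = as.integer(d_latent), epochs = as.integer(epochs),
       lr = lr, batch_size = as.integer(batch_size),
       n_max = as.integer(n_max), seed = as.integer(seed))
}

gstn_init_params <- function(config, d_in) {
  H <- config$n_heads
  T_ <- length(config$kinds)
  dims <- c(d_in, rep(config$d_latent, config$n_layers))
  # near-equal attention shares at start; small noise breaks the symmetry
  # between heads (identical heads would receive identical updates)
  params <- list(R = matrix(stats::rnorm(H * T_, sd = 0.01), H, T_))
  for (l in seq_len(config$n_layers)) {
    params[[paste0("W", l)]] <- glorot_init(dims[l], dims[l + 1])
  }
  d_flat <- config$n_max * config$d_latent
  params$U1 <- glorot_init(d_flat, config$hidden)
  params$b1 <- numeric(config$hidden)
  params$U2 <- glorot_init(config$hidden, 2L)
  params$b2 <- numeric(2L)
  params
}

gstn_conv_weights <- function(params, config) {
  lapply(seq_len(config$n_layers), function(l) params[[paste0("W", l)]])
}

# ---- per-molecule graph stage (unpadded fast path) -------------------------

gstn_graph_stage <- function(inp, params, config) {
  W <- softmax_rows(params$R)               # n_heads x T, rows sum to 1
  G <- inp$G
  n <- inp$n
  H <- config$n_heads
  Qk <- vector("list", H)
  for (k in seq_len(H)) {
    Q <- W[k, 1] * G[[1]]
    for (i in seq_along(G)[-1]) Q <- Q + W[k, i] * G[[i]]
    Qk[[k]] <- Q
  }
  prefix <- vector("list", H)               # prefix[[k]] = Q_1 ... Q_k
  prefix[[1]] <- Qk[[1]]
  if (H > 1) for (k in 2:H) prefix[[k]] <- prefix[[k - 1]] %*% Qk[[k]]
  Qp <- prefix[[H]]

  S <- (Qp + t(Qp)) / 2
  diag(S) <- diag(S) + 1                    # S here caches Q_p-hat (S + I)
  d <- rowSums(S)
  dm <- 1 / sqrt(d)
  Qt <- S * outer(dm, dm)

  L <- config$n_layers
  conv <- gstn_conv_weights(params, config)
  Zs <- vector("list", L + 1)               # Zs[[1]] = X
  Bs <- vector("list", L)                   # Bs[[l]] = Z_{l-1} %*% W_l
  Zps <- vector("list", L)
  Zs[[1]] <- inp$X
  for (l in seq_len(L)) {
    Bs[[l]] <- Zs[[l]] %*% conv[[l]]
    Zps[[l]] <- Qt %*% Bs[[l]]
    Zs[[l + 1]] <- relu(Zps[[l]])
  }
  list(W = W, Qk = Qk, prefix = prefix, Qp = Qp, Sh = S, d = d, dm = dm,
       Qt = Qt, Zs = Zs, Bs = Bs, Zps = Zps, latent = Zs[[L + 1]], n = n)
}

# dZL: gradient w.r.t. the final latent block (n x d_latent); accumulates
# into grads (environment-like list returned)
gstn_graph_backward <- function(inp, cache, dZL, params, config) {
  L <- config$n_layers
  conv <- gstn_conv_weights(params, config)
  n <- inp$n
  Qt <- cache$Qt
  dQt <- matrix(0, n, n)
  gW <- vector("list", L)
  dZ <- dZL
  for (l in rev(seq_len(L))) {
    dZp <- dZ * (cache$Zps[[l]] > 0)
    dQt <- dQt + tcrossprod(dZp, cache$Bs[[l]])
    dB <- crossprod(Qt, dZp)
    gW[[l]] <- crossprod(cache$Zs[[l]], dB)
    dZ <- tcrossprod(dB, conv[[l]])
  }

  # propagator normalization: Qt = Sh * outer(dm, dm), d = rowSums(Sh)
  T1 <- dQt * cache$Sh
  ddm <- as.vector(T1 %*% cache$dm + crossprod(T1, cache$dm))
  dd <- -0.5 * ddm * cache$d^(-1.5)
  dSh <- dQt * outer(cache$dm, cache$dm) + matrix(dd, n, n)
  dQp <- (dSh + t(dSh)) / 2               # symmetrization; +I shift is constant

  H <- config$n_heads
  suffix <- vector("list", H + 1)          # suffix[[k]] = Q_k ... Q_H
  suffix[[H + 1]] <- diag(n)
  for (k in rev(seq_len(H))) suffix[[k]] <- cache$Qk[[k]] %*% suffix[[k + 1]]
  dw <- matrix(0, H, length(inp$G))
  for (k in seq_len(H)) {
    left <- if (k == 1) dQp else crossprod(cache$prefix[[k - 1]], dQp)
    dQk <- left %*% t(suffix[[k + 1]])
    for (i in seq_along(inp$G)) dw[k, i] <- sum(dQk * inp$G[[i]])
  }
  w <- cache$W
  gR <- w * (dw - rowSums(w * dw))         # softmax backward, per head
  list(gR = gR, gW = gW)
}

# ---- fitting ---------------------------------------------------------------

resolve_training_frame <- function(data) {
  if (inherits(data, "gstn_dataset")) data <- data$records
  stopifnot(is.data.frame(data), all(c("smiles", "label") %in% names(data)))
  data
}

#' Fit a graph subgraph transformer network
#'
#' Trains the subgraph-biased graph transformer classifier: the molecular
#' adjacency matrix is decomposed into the predefined subgraphs in `kinds`,
#' each attention head combines them through softmax-normalized learnable
#' weights into a meta-path matrix, the heads' meta-paths are multiplied
#' into `Q_p`, and a symmetrically normalized graph convolution over `Q_p`
#' followed by a flatten + MLP head produces blocker probabilities.
#' Training minimizes cross-entropy with Adam; all randomness (weight
#' initialization, batch shuffling) is governed by `seed`.
#'
#' @param data a [build_dataset()] result or a data frame with columns
#'   `smiles` and `label` (values `"blocker"` / `"non_blocker"`).
#' @param kinds ordered subset of [subgraph_kinds()].
#' @param n_heads number of attention heads (meta-paths multiplied).
#' @param n_layers graph-convolution depth.
#' @param hidden MLP hidden width.
#' @param d_latent latent (per-atom) feature dimension.
#' @param epochs,lr,batch_size optimizer settings.
#' @param n_max padded molecule size; molecules at or above it are rejected.
#' @param seed integer seed; identical seeds give bit-identical fits.
#' @param verbose print the epoch loss?
#' @return an object of class `gstn` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods.
#' @seealso [gtn_baseline()], [mgcnn()], [ecfp_svm()], [cross_validate()]
#' @export
gstn <- function(data, kinds = subgraph_kinds(), n_heads = 2L, n_layers = 2L,
                 hidden = 128L, d_latent = 64L, epochs = 100L, lr = 1e-3,
                 batch_size = 64L, n_max = 45L, seed = 1L, verbose = FALSE) {
  df <- resolve_training_frame(data)
  config <- gstn_config(kinds, n_heads, n_layers, hidden, d_latent, epochs,
                        lr, batch_size, n_max, seed)
  classes <- c("non_blocker", "blocker")
  y <- match(df$label, classes)
  if (any(is.na(y))) stop("labels must be 'blocker' or 'non_blocker'")
  if (length(unique(y)) < 2L) {
    stop("training requires both classes to be present", call. = FALSE)
  }
  mols <- parse_molecules(df$smiles, on_error = "stop")
  inputs <- lapply(mols, prepare_mol_input, kinds = kinds, n_max = n_max)

  set.seed(seed)
  params <- gstn_init_params(config, d_in = feature_dim())
  state <- adam_state(params)
  step <- 0L
  loss_history <- numeric(epochs)
  n <- length(inputs)
  Y <- diag(2)[y, , drop = FALSE]

  for (epoch in seq_len(epochs)) {
    batches <- epoch_batches(n, config$batch_size)
    epoch_loss <- 0
    for (batch in batches) {
      B <- length(batch)
      caches <- vector("list", B)
      V <- matrix(0, B, config$n_max * config$d_latent)
      for (b in seq_len(B)) {
        caches[[b]] <- gstn_graph_stage(inputs[[batch[b]]], params, config)
        V[b, ] <- flatten_latent(caches[[b]]$latent, config$n_max)
      }
      hf <- head_forward(V, params)
      loss <- cross_entropy(hf$P, y[batch])
      epoch_loss <- epoch_loss + loss * B
      dlogits <- (hf$P - Y[batch, , drop = FALSE]) / B
      hb <- head_backward(V, hf, dlogits, params)
      grads <- list(R = params$R * 0, U1 = hb$gU1, b1 = hb$gb1,
                    U2 = hb$gU2, b2 = hb$gb2)
      for (l in seq_len(config$n_layers)) {
        grads[[paste0("W", l)]] <- params[[paste0("W", l)]] * 0
      }
      for (b in seq_len(B)) {
        inp <- inputs[[batch[b]]]
        dZL <- matrix(hb$dV[b, seq_len(inp$n * config$d_latent)],
                      nrow = inp$n, ncol = config$d_latent, byrow = TRUE)
        gb <- gstn_graph_backward(inp, caches[[b]], dZL, params, config)
        grads$R <- grads$R + gb$gR
        for (l in seq_len(config$n_layers)) {
          grads[[paste0("W", l)]] <- grads[[paste0("W", l)]] + gb$gW[[l]]
        }
      }
      step <- step + 1L
      upd <- adam_step(params, grads, state, config$lr, step)
      params <- upd$params
      state <- upd$state
    }
    loss_history[epoch] <- epoch_loss / n
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f", epoch, loss_history[epoch]))
    }
  }

  structure(
    list(config = config, kinds = kinds, classes = classes, params = params,
         d_in = feature_dim(), loss_history = loss_history,
         n_train = n),
    class = "gstn"
  )
}

# ---- prediction ------------------------------------------------------------

resolve_smiles <- function(newdata) {
  if (inherits(newdata, "gstn_dataset")) return(newdata$records$smiles)
  if (is.data.frame(newdata)) {
    stopifnot("smiles" %in% names(newdata))
    return(as.character(newdata$smiles))
  }
  as.character(newdata)
}

gstn_predict_core <- function(object, smiles) {
  if (is.null(object$params)) stop("model has no parameters (not fitted)")
  config <- object$config
  mols <- parse_molecules(smiles, on_error = "stop")
  inputs <- lapply(mols, prepare_mol_input, kinds = object$kinds,
                   n_max = config$n_max)
  B <- length(inputs)
  V <- matrix(0, B, config$n_max * config$d_latent)
  latents <- matrix(0, B, config$d_latent)
  for (b in seq_len(B)) {
    cache <- gstn_graph_stage(inputs[[b]], object$params, config)
    V[b, ] <- flatten_latent(cache$latent, config$n_max)
    latents[b, ] <- colMeans(cache$latent)   # masked mean over real atoms
  }
  hf <- head_forward(V, object$params)
  colnames(hf$P) <- object$classes
  list(P = hf$P, latents = latents)
}

#' Predict from a fitted subgraph transformer
#'
#' @param object a fitted `gstn` model.
#' @param newdata SMILES character vector, a data frame with a `smiles`
#'   column, or a `gstn_dataset`.
#' @param type `"prob"` for the blocker probability, `"class"` for hard
#'   labels, `"latent"` for the 64-dimensional molecular fingerprints
#'   (masked mean over the real-atom rows of the final convolution layer).
#' @param ... unused.
#' @return numeric vector, character vector, or latent matrix.
#' @export
predict.gstn <- function(object, newdata,
                         type = c("prob", "class", "latent"), ...) {
  type <- match.arg(type)
  smiles <- resolve_smiles(newdata)
  core <- gstn_predict_core(object, smiles)
  switch(type,
    prob = core$P[, "blocker"],
    class = object$classes[max.col(core$P, ties.method = "first")],
    latent = core$latents
  )
}

#' Forward pass on explicit graph and tensor objects
#'
#' Runs one molecule through a fitted model using the padded
#' [build_graph()] / [build_subgraph_tensor()] representations; the result
#' is a probability vector over the two classes. Deterministic given fixed
#' parameters.
#'
#' @param model fitted `gstn`.
#' @param graph a `gstn_graph`.
#' @param tensor the matching `gstn_tensor` (kinds must equal the model's).
#' @return named numeric vector of class probabilities (sums to 1).
#' @export
gstn_forward <- function(model, graph, tensor) {
  stopifnot(inherits(model, "gstn"), inherits(graph, "gstn_graph"),
            inherits(tensor, "gstn_tensor"))
  if (is.null(model$params)) stop("model has no parameters (not fitted)")
  if (!identical(tensor$kinds, model$kinds)) {
    stop("tensor kinds do not match the model's kinds", call. = FALSE)
  }
  inp <- list(n = graph$n_real,
              X = graph$X[seq_len(graph$n_real), , drop = FALSE],
              G = lapply(tensor_slices(tensor), function(G) {
                G[seq_len(graph$n_real), seq_len(graph$n_real), drop = FALSE]
              }))
  cache <- gstn_graph_stage(inp, model$params, model$config)
  V <- matrix(flatten_latent(cache$latent, model$config$n_max), nrow = 1L)
  p <- head_forward(V, model$params)$P[1L, ]
  names(p) <- model$classes
  p
}

# ---- interpretation --------------------------------------------------------

#' Learned subgraph weight shares
#'
#' Per-kind attention shares: the softmax-normalized weights of each head,
#' averaged over heads (and, if given, over fold models). Shares sum to 1.
#'
#' @param model fitted `gstn`.
#' @param over_folds optional list of additional fitted models (e.g. the
#'   per-fold models of a cross-validation) averaged in.
#' @return named numeric vector, one share per subgraph kind.
#' @export
subgraph_weight_shares <- function(model, over_folds = NULL) {
  models <- c(list(model), over_folds)
  shares <- sapply(models, function(m) {
    colMeans(softmax_rows(m$params$R))
  })
  out <- rowMeans(matrix(shares, nrow = length(model$kinds)))
  names(out) <- model$kinds
  out
}

#' Interpretation matrices for one molecule
#'
#' Extracts the subgraph slices `G_i`, the per-head meta-paths
#' `Q_1 ... Q_n`, and their product `Q_p` exactly as used in the forward
#' pass, padded to `n_max`.
#'
#' @param model fitted `gstn`.
#' @param smiles a single SMILES string (or a `gstn_molecule`).
#' @return list with `G` (named list of slices), `Q` (per-head meta-paths),
#'   `Q_p`, `kinds`, `n_real`.
#' @export
interpretation_matrices <- function(model, smiles) {
  stopifnot(inherits(model, "gstn"))
  mol <- if (inherits(smiles, "gstn_molecule")) smiles else parse_molecule(smiles)
  graph <- build_graph(mol, n_max = model$config$n_max)
  tensor <- build_subgraph_tensor(graph, mol, model$kinds)
  W <- softmax_rows(model$params$R)
  G <- tensor_slices(tensor)
  names(G) <- model$kinds
  Q <- lapply(seq_len(nrow(W)), function(k) meta_path(tensor, W[k, ]))
  names(Q) <- paste0("Q_", seq_along(Q))
  list(G = G, Q = Q, Q_p = Reduce(`%*%`, Q), kinds = model$kinds,
       n_real = graph$n_real)
}

#' Latent molecular fingerprints
#'
#' The 64-dimensional per-molecule vectors from the final graph-convolution
#' layer (masked mean over real atoms), used as molecular fingerprints for
#' applicability-domain analysis.
#'
#' @param model fitted `gstn`.
#' @param smiles character vector of SMILES.
#' @return numeric matrix `length(smiles) x d_latent`.
#' @export
latent_features <- function(model, smiles) {
  gstn_predict_core(model, resolve_smiles(smiles))$latents
}

# ---- methods ---------------------------------------------------------------

#' @export
print.gstn <- function(x, ...) {
  cat("Graph subgraph transformer network\n")
  cat("  subgraphs (T = ", length(x$kinds), "): ",
      paste(x$kinds, collapse = ", "), "\n", sep = "")
  cat("  heads: ", x$config$n_heads, ", conv layers: ", x$config$n_layers,
      " (latent ", x$config$d_latent, "), MLP hidden: ", x$config$hidden,
      "\n", sep = "")
  cat("  trained on ", x$n_train, " molecules, ", x$config$epochs,
      " epochs; final loss ",
      format(utils::tail(x$loss_history, 1), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gstn <- function(object, ...) {
  shares <- subgraph_weight_shares(object)
  out <- list(model = object, shares = shares,
              per_head = softmax_rows(object$params$R))
  class(out) <- "summary.gstn"
  out
}

#' @export
print.summary.gstn <- function(x, ...) {
  print(x$model)
  cat("  subgraph attention shares (mean over heads):\n")
  print(round(x$shares, 4))
  invisible(x)
}

#' @export
coef.gstn <- function(object, ...) {
  W <- softmax_rows(object$params$R)
  dimnames(W) <- list(paste0("head_", seq_len(nrow(W))), object$kinds)
  W
}

#' @export
plot.gstn <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "mean cross-entropy",
                 main = "Training loss", ...)
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

serialize_param <- function(p) {
  if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
  else list(dim = length(p), data = as.vector(p))
}

deserialize_param <- function(s) {
  d <- unlist(s$dim)
  x <- as.numeric(unlist(s$data))
  if (length(d) == 2L) matrix(x, d[1], d[2]) else x
}

#' Save / load a fitted model
#'
#' Models are stored as a self-describing JSON archive (configuration,
#' subgraph kinds, and all weight tensors at full precision); reloading
#' reproduces bit-identical predictions.
#'
#' @param model fitted `gstn`.
#' @param path file path for the archive.
#' @return `save_gstn` returns `path` invisibly; `load_gstn` returns the
#'   model.
#' @export
save_gstn <- function(model, path) {
  stopifnot(inherits(model, "gstn"))
  payload <- list(
    format = "gstn-model", version = 1L,
    config = model$config, kinds = model$kinds, classes = model$classes,
    d_in = model$d_in, n_train = model$n_train,
    loss_history = model$loss_history,
    params = lapply(model$params, serialize_param)
  )
  # 17 significant digits guarantee an exact double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_gstn
#' @export
load_gstn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "gstn-model")) {
    stop("not a model archive: ", path, call. = FALSE)
  }
  config <- payload$config
  config$kinds <- unlist(config$kinds)
  for (nm in setdiff(names(config), c("kinds", "lr"))) {
    config[[nm]] <- as.integer(config[[nm]])
  }
  config$lr <- as.numeric(config$lr)
  structure(
    list(config = config, kinds = unlist(payload$kinds),
         classes = unlist(payload$classes),
         params = lapply(payload$params, deserialize_param),
         d_in = as.integer(payload$d_in),
         loss_history = as.numeric(unlist(payload$loss_history)),
         n_train = as.integer(payload$n_train)),
    class = "gstn"
  )
}
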