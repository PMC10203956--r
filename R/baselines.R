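# Baseline models: GTN (single-subgraph transformer), MGCNN (plain graph
# convolution with batch normalization), and ECFP + SVM. All expose the
# same predict contract as the subgraph transformer.

#' Graph transformer baseline (1T)
#'
#' The subgraph transformer without predefined substructures: only the
#' `all_atoms` slice is used, everything else is identical to [gstn()].
#' With a single head the graph-transformer stage reduces exactly to
#' `Q_p = A`.
#'
#' @inheritParams gstn
#' @param ... passed to [gstn()].
#' @return a fitted model of class `c("gtn", "gstn")`.
#' @export
gtn_baseline <- function(data, ...) {
  fit <- gstn(data, kinds = "all_atoms", ...)
  class(fit) <- c("gtn", class(fit))
  fit
}

# ---- MGCNN -----------------------------------------------------------------

mgcnn_propagator <- function(inp) {
  A <- inp$G[[1]]
  diag(A) <- diag(A) + 1
  d <- rowSums(A)
  dm <- 1 / sqrt(d)
  A * outer(dm, dm)
}

bn_forward <- function(C, gamma, beta, eps = 1e-5) {
  mu <- colMeans(C)
  xc <- sweep(C, 2L, mu)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, `*`)
  out <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = out, xhat = xhat, xc = xc, invstd = invstd, mu = mu, v = v)
}

bn_backward <- function(cache, dout, gamma) {
  N <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, gamma, `*`)
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_xhat <- colSums(dxhat * cache$xhat)
  dx <- sweep(
    N * dxhat -
      matrix(sum_dxhat, N, length(sum_dxhat), byrow = TRUE) -
      sweep(cache$xhat, 2L, sum_dxhat_xhat, `*`),
    2L, cache$invstd / N, `*`
  )
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_infer <- function(C, gamma, beta, rm, rv, eps = 1e-5) {
  xhat <- sweep(sweep(C, 2L, rm), 2L, 1 / sqrt(rv + eps), `*`)
  sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
}

#' Molecular graph convolutional network baseline
#'
#' A plain two-layer graph convolutional network on the raw adjacency
#' matrix (`A + I`, symmetrically normalized), with per-layer batch
#' normalization and the same flatten + MLP decision head as [gstn()].
#' Uses the identical atom features and layer widths, so the only
#' difference from the subgraph transformer is the propagator — isolating
#' the effect of the subgraph bias.
#'
#' @inheritParams gstn
#' @return an object of class `mgcnn` implementing the shared predict
#'   contract.
#' @export
mgcnn <- function(data, n_layers = 2L, hidden = 128L, d_latent = 64L,
                  epochs = 100L, lr = 1e-3, batch_size = 64L, n_max = 45L,
                  seed = 1L, verbose = FALSE) {
  df <- resolve_training_frame(data)
  config <- gstn_config(kinds = "all_atoms", n_heads = 1L,
                        n_layers = n_layers, hidden = hidden,
                        d_latent = d_latent, epochs = epochs, lr = lr,
                        batch_size = batch_size, n_max = n_max, seed = seed)
  classes <- c("non_blocker", "blocker")
  y <- match(df$label, classes)
  if (any(is.na(y))) stop("labels must be 'blocker' or 'non_blocker'")
  if (length(unique(y)) < 2L) {
    stop("training requires both classes to be present", call. = FALSE)
  }
  mols <- parse_molecules(df$smiles, on_error = "stop")
  inputs <- lapply(mols, prepare_mol_input, kinds = "all_atoms", n_max = n_max)
  props <- lapply(inputs, mgcnn_propagator)

  set.seed(seed)
  d_in <- feature_dim()
  dims <- c(d_in, rep(config$d_latent, n_layers))
  params <- list()
  for (l in seq_len(n_layers)) {
    params[[paste0("W", l)]] <- glorot_init(dims[l], dims[l + 1])
    params[[paste0("g", l)]] <- rep(1, dims[l + 1])
    params[[paste0("be", l)]] <- rep(0, dims[l + 1])
  }
  d_flat <- config$n_max * config$d_latent
  params$U1 <- glorot_init(d_flat, hidden)
  params$b1 <- numeric(hidden)
  params$U2 <- glorot_init(hidden, 2L)
  params$b2 <- numeric(2L)
  running <- lapply(seq_len(n_layers), function(l) {
    list(mean = rep(0, dims[l + 1]), var = rep(1, dims[l + 1]))
  })
  momentum <- 0.9

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
      rows <- vapply(inputs[batch], `[[`, integer(1), "n")
      offsets <- c(0L, cumsum(rows))
      # layer-wise forward with cross-molecule batch normalization
      Z <- lapply(inputs[batch], `[[`, "X")
      layer_caches <- vector("list", n_layers)
      for (l in seq_len(n_layers)) {
        W <- params[[paste0("W", l)]]
        Cs <- lapply(seq_len(B), function(b) props[[batch[b]]] %*% (Z[[b]] %*% W))
        Cstack <- do.call(rbind, Cs)
        bn <- bn_forward(Cstack, params[[paste0("g", l)]],
                         params[[paste0("be", l)]])
        running[[l]]$mean <- momentum * running[[l]]$mean +
          (1 - momentum) * bn$mu
        running[[l]]$var <- momentum * running[[l]]$var +
          (1 - momentum) * bn$v
        act <- relu(bn$out)
        layer_caches[[l]] <- list(Zin = Z, bn = bn, pre = bn$out)
        Z <- lapply(seq_len(B), function(b) {
          act[(offsets[b] + 1L):offsets[b + 1L], , drop = FALSE]
        })
      }
      V <- matrix(0, B, d_flat)
      for (b in seq_len(B)) V[b, ] <- flatten_latent(Z[[b]], config$n_max)
      hf <- head_forward(V, params)
      loss <- cross_entropy(hf$P, y[batch])
      epoch_loss <- epoch_loss + loss * B
      dlogits <- (hf$P - Y[batch, , drop = FALSE]) / B
      hb <- head_backward(V, hf, dlogits, params)
      grads <- list(U1 = hb$gU1, b1 = hb$gb1, U2 = hb$gU2, b2 = hb$gb2)
      dZ <- lapply(seq_len(B), function(b) {
        inp <- inputs[[batch[b]]]
        matrix(hb$dV[b, seq_len(inp$n * config$d_latent)],
               nrow = inp$n, ncol = config$d_latent, byrow = TRUE)
      })
      for (l in rev(seq_len(n_layers))) {
        lc <- layer_caches[[l]]
        dact <- do.call(rbind, dZ)
        dpre <- dact * (lc$pre > 0)
        bb <- bn_backward(lc$bn, dpre, params[[paste0("g", l)]])
        grads[[paste0("g", l)]] <- bb$dgamma
        grads[[paste0("be", l)]] <- bb$dbeta
        W <- params[[paste0("W", l)]]
        gW <- W * 0
        dZprev <- vector("list", B)
        for (b in seq_len(B)) {
          dC <- bb$dx[(offsets[b] + 1L):offsets[b + 1L], , drop = FALSE]
          dB_ <- crossprod(props[[batch[b]]], dC)
          gW <- gW + crossprod(lc$Zin[[b]], dB_)
          dZprev[[b]] <- tcrossprod(dB_, W)
        }
        grads[[paste0("W", l)]] <- gW
        dZ <- dZprev
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
    list(config = config, classes = classes, params = params,
         running = running, n_layers = n_layers, d_in = d_in,
         loss_history = loss_history, n_train = n),
    class = "mgcnn"
  )
}

#' @export
predict.mgcnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  smiles <- resolve_smiles(newdata)
  config <- object$config
  mols <- parse_molecules(smiles, on_error = "stop")
  inputs <- lapply(mols, prepare_mol_input, kinds = "all_atoms",
                   n_max = config$n_max)
  B <- length(inputs)
  V <- matrix(0, B, config$n_max * config$d_latent)
  for (b in seq_len(B)) {
    P <- mgcnn_propagator(inputs[[b]])
    Z <- inputs[[b]]$X
    for (l in seq_len(object$n_layers)) {
      C <- P %*% (Z %*% object$params[[paste0("W", l)]])
      Z <- relu(bn_infer(C, object$params[[paste0("g", l)]],
                         object$params[[paste0("be", l)]],
                         object$running[[l]]$mean, object$running[[l]]$var))
    }
    V[b, ] <- flatten_latent(Z, config$n_max)
  }
  P2 <- head_forward(V, object$params)$P
  colnames(P2) <- object$classes
  if (type == "prob") P2[, "blocker"] else {
    object$classes[max.col(P2, ties.method = "first")]
  }
}

#' @export
print.mgcnn <- function(x, ...) {
  cat("Molecular graph convolutional network (", x$n_layers,
      " conv layers + batch norm)\n", sep = "")
  cat("  trained on ", x$n_train, " molecules; final loss ",
      format(utils::tail(x$loss_history, 1), digits = 4), "\n", sep = "")
  invisible(x)
}

# ---- ECFP + SVM ------------------------------------------------------------

#' ECFP + support vector machine baseline
#'
#' Circular fingerprints (1,024 bits, diameter 4, i.e. Morgan radius 2)
#' fed to a radial-basis support vector machine with probability outputs.
#'
#' @inheritParams gstn
#' @param n_bits,diameter fingerprint settings.
#' @param cost SVM regularization constant.
#' @param gamma radial-basis kernel width. Squared Hamming distances
#'   between hashed 1024-bit circular fingerprints are of order tens, so
#'   the usual `1/n_bits` default would make the kernel nearly constant;
#'   0.01 puts typical distances on the kernel's active scale.
#' @return an object of class `ecfp_svm` implementing the shared predict
#'   contract.
#' @export
ecfp_svm <- function(data, n_bits = 1024L, diameter = 4L, cost = 1,
                     gamma = 0.01, seed = 1L) {
  df <- resolve_training_frame(data)
  classes <- c("non_blocker", "blocker")
  y <- factor(df$label, levels = classes)
  if (any(is.na(y))) stop("labels must be 'blocker' or 'non_blocker'")
  if (nlevels(droplevels(y)) < 2L) {
    stop("training requires both classes to be present", call. = FALSE)
  }
  fp <- ecfp(df$smiles, n_bits = n_bits, diameter = diameter)
  set.seed(seed)
  fit <- e1071::svm(x = fp, y = y, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  structure(
    list(svm = fit, n_bits = n_bits, diameter = diameter, classes = classes,
         n_train = nrow(df)),
    class = "ecfp_svm"
  )
}

#' @export
#' @describeIn ecfp_svm blocker probabilities are the SVM decision margin
#'   squashed through a logistic link (Platt-style probability fitting is
#'   unstable on small training sets), so `p >= 0.5` agrees exactly with
#'   the decision boundary.
predict.ecfp_svm <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  smiles <- resolve_smiles(newdata)
  fp <- ecfp(smiles, n_bits = object$n_bits, diameter = object$diameter)
  pred <- stats::predict(object$svm, fp, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # positive decision values favor the class named first in the column
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  margin <- if (identical(first, "blocker")) dv[, 1] else -dv[, 1]
  p_blocker <- unname(stats::plogis(margin))
  if (type == "prob") p_blocker else {
    ifelse(p_blocker >= 0.5, "blocker", "non_blocker")
  }
}

#' @export
print.ecfp_svm <- function(x, ...) {
  cat("ECFP(", x$n_bits, " bits, diameter ", x$diameter,
      ") + radial SVM, trained on ", x$n_train, " molecules\n", sep = "")
  invisible(x)
}
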