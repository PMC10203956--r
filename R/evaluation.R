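# Confusion metrics, ROC AUC, stratified cross-validation, scheme
# comparison, and applicability-domain leverage.

#' Confusion counts
#'
#' @param y_true,y_pred character vectors of `"blocker"` /
#'   `"non_blocker"` labels (the blocker class is positive).
#' @param positive name of the positive class.
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred, positive = "blocker") {
  stopifnot(length(y_true) == length(y_pred))
  pt <- y_true == positive
  pp <- y_pred == positive
  structure(
    list(tp = sum(pt & pp), fp = sum(!pt & pp),
         tn = sum(!pt & !pp), fn = sum(pt & !pp)),
    class = "gstn_confusion"
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN), Precision = TP / (TP + FP),
#' Recall = TP / (TP + FN), F1 = harmonic mean of precision and recall.
#' Undefined ratios (zero denominators) are reported as `NA` with a
#' warning rather than silently as 0.
#'
#' @param c a `gstn_confusion` (or list with `tp`, `fp`, `tn`, `fn`).
#' @return list with `accuracy`, `precision`, `recall`, `f1` and a logical
#'   `undefined` flag vector.
#' @export
classification_metrics <- function(c) {
  tp <- c$tp; fp <- c$fp; tn <- c$tn; fn <- c$fn
  total <- tp + fp + tn + fn
  undefined <- c(precision = tp + fp == 0, recall = tp + fn == 0)
  accuracy <- if (total > 0) (tp + tn) / total else NA_real_
  precision <- if (undefined[["precision"]]) NA_real_ else tp / (tp + fp)
  recall <- if (undefined[["recall"]]) NA_real_ else tp / (tp + fn)
  f1 <- if (anyNA(c(precision, recall)) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  if (any(undefined)) {
    warning("undefined metric(s): ",
            paste(names(undefined)[undefined], collapse = ", "),
            " (zero denominator); reported as NA")
  }
  list(accuracy = accuracy, precision = precision, recall = recall, f1 = f1,
       undefined = undefined)
}

#' ROC AUC (rank statistic)
#'
#' Pairwise-concordance formulation: the probability that a random
#' positive scores above a random negative, ties counted one half.
#'
#' @param y_true labels (positive class `"blocker"`, or logical/0-1).
#' @param scores numeric scores (higher = more blocker-like).
#' @param positive positive class label.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores, positive = "blocker") {
  pos <- if (is.logical(y_true)) y_true else
    if (is.numeric(y_true)) y_true == 1 else y_true == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold assignment
#'
#' Splits samples into `k` disjoint folds so that per-fold class counts
#' differ from exact proportionality by at most one.
#'
#' @param labels label vector (or a `gstn_dataset`).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  if (inherits(labels, "gstn_dataset")) labels <- labels$records$label
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class needs at least k = ", k, " samples; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

model_fitters <- function() {
  list(
    gstn = function(df, seed, ...) gstn(df, seed = seed, ...),
    gtn = function(df, seed, ...) gtn_baseline(df, seed = seed, ...),
    mgcnn = function(df, seed, ...) mgcnn(df, seed = seed, ...),
    ecfp_svm = function(df, seed, ...) ecfp_svm(df, seed = seed, ...)
  )
}

#' Stratified k-fold cross-validation
#'
#' Trains the chosen model on each training split and evaluates on the
#' held-out fold. Reports per-fold metrics, their mean and standard
#' deviation, and the fold-pooled metrics over all held-out predictions
#' (both conventions are emitted, labeled).
#'
#' @param ds a `gstn_dataset` (or data frame with `smiles`, `label`).
#' @param model one of `"gstn"`, `"gtn"`, `"mgcnn"`, `"ecfp_svm"`.
#' @param k number of folds.
#' @param seed integer seed (folds and per-fold model seeds derive from it).
#' @param keep_models keep the fitted fold models (needed for
#'   fold-averaged subgraph weight shares)?
#' @param ... passed to the model fitting function.
#' @return an object of class `gstn_cv`: `folds` (assignment), `per_fold`
#'   (data frame), `mean`, `sd`, `pooled`, `models` (if kept),
#'   `predictions`.
#' @export
cross_validate <- function(ds, model = c("gstn", "gtn", "mgcnn", "ecfp_svm"),
                           k = 10L, seed = 1L, keep_models = FALSE, ...) {
  model <- match.arg(model)
  df <- resolve_training_frame(ds)
  fold <- stratified_kfold(df$label, k = k, seed = seed)
  fitter <- model_fitters()[[model]]
  per_fold <- vector("list", k)
  models <- vector("list", k)
  pred_all <- data.frame(idx = seq_len(nrow(df)), p_blocker = NA_real_,
                         label = NA_character_, fold = fold)
  for (f in seq_len(k)) {
    train <- df[fold != f, , drop = FALSE]
    test <- df[fold == f, , drop = FALSE]
    fit <- fitter(train, seed = seed + f, ...)
    p <- predict(fit, test$smiles, type = "prob")
    pred <- ifelse(p >= 0.5, "blocker", "non_blocker")
    cm <- classification_metrics(confusion(test$label, pred))
    per_fold[[f]] <- data.frame(
      fold = f, n = nrow(test),
      accuracy = cm$accuracy, precision = cm$precision,
      recall = cm$recall, f1 = cm$f1,
      auc = roc_auc(test$label, p)
    )
    pred_all$p_blocker[fold == f] <- p
    pred_all$label[fold == f] <- pred
    if (keep_models) models[[f]] <- fit
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auc")
  pooled_cm <- classification_metrics(confusion(df$label, pred_all$label))
  pooled <- c(unlist(pooled_cm[c("accuracy", "precision", "recall", "f1")]),
              auc = roc_auc(df$label, pred_all$p_blocker))
  structure(
    list(model = model, k = k, seed = seed, folds = fold,
         per_fold = per_fold,
         mean = colMeans(per_fold[metric_cols], na.rm = TRUE),
         sd = apply(per_fold[metric_cols], 2L, stats::sd, na.rm = TRUE),
         pooled = pooled,
         predictions = pred_all,
         models = if (keep_models) models else NULL),
    class = "gstn_cv"
  )
}

#' @export
print.gstn_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation, model = ", x$model, "\n", sep = "")
  cat("  fold-averaged metrics (mean +/- sd):\n")
  for (m in names(x$mean)) {
    cat(sprintf("    %-9s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Compare two schemes by fold-level t-test
#'
#' Welch two-sample t-test on fold-level metric values of two
#' cross-validation runs (e.g. two thresholding schemes).
#'
#' @param fold_metrics_a,fold_metrics_b numeric vectors of fold-level
#'   metric values, or `gstn_cv` objects (then `metric` selects a column).
#' @param metric metric column when `gstn_cv` objects are given.
#' @return list with `t`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_schemes <- function(fold_metrics_a, fold_metrics_b, metric = "f1") {
  get_vals <- function(x) {
    if (inherits(x, "gstn_cv")) x$per_fold[[metric]] else as.numeric(x)
  }
  a <- get_vals(fold_metrics_a)
  b <- get_vals(fold_metrics_b)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Applicability-domain leverage
#'
#' Computes the leverage `h_i = x_i (X'X)^{-1} x_i'` of query fingerprints
#' against the training fingerprint matrix `X` (M molecules x D latent
#' features). A query with `h > 3 D / M` needs substantial extrapolation
#' and is flagged as chemically different from the training set. When
#' `X'X` is rank-deficient the Moore-Penrose pseudo-inverse is used and
#' reported via `used_pseudoinverse`.
#'
#' @param train_latents numeric matrix `M x D` of training fingerprints.
#' @param query_latents numeric matrix (or vector) of query fingerprints;
#'   defaults to the training matrix itself (self-leverage).
#' @return an object of class `gstn_leverage`: `h`, `threshold`, `flags`,
#'   `used_pseudoinverse`, `M`, `D`.
#' @export
leverage <- function(train_latents, query_latents = train_latents) {
  X <- as.matrix(train_latents)
  Q <- query_latents
  if (is.vector(Q)) Q <- matrix(Q, nrow = 1L)
  Q <- as.matrix(Q)
  stopifnot(ncol(Q) == ncol(X))
  M <- nrow(X)
  D <- ncol(X)
  XtX <- crossprod(X)
  inv <- tryCatch(solve(XtX), error = function(e) NULL)
  used_pinv <- is.null(inv)
  if (used_pinv) inv <- MASS::ginv(XtX)
  h <- rowSums((Q %*% inv) * Q)
  threshold <- 3 * D / M
  structure(
    list(h = h, threshold = threshold, flags = h > threshold,
         used_pseudoinverse = used_pinv, M = M, D = D),
    class = "gstn_leverage"
  )
}

#' @export
print.gstn_leverage <- function(x, ...) {
  cat("<leverage> ", length(x$h), " queries vs M = ", x$M, ", D = ", x$D,
      "; threshold 3D/M = ", format(x$threshold, digits = 4), "\n", sep = "")
  cat("  flagged outside the applicability domain: ", sum(x$flags), "\n",
      sep = "")
  invisible(x)
}
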