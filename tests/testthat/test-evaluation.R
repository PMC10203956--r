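test_that("confusion counts match per-element enumeration", {
  y <- c("blocker", "blocker", "non_blocker", "non_blocker")
  cm <- confusion(y, y)
  expect_equal(cm$fp + cm$fn, 0L)
  expect_equal(cm$tp, 2L)

  flipped <- ifelse(y == "blocker", "non_blocker", "blocker")
  cm2 <- confusion(y, flipped)
  expect_equal(cm2$tp, 0L)
  expect_equal(cm2$fn, cm$tp)
  expect_equal(cm2$fp, cm$tn)

  set.seed(13)
  for (rep in 1:20) {
    yt <- sample(c("blocker", "non_blocker"), 30, replace = TRUE)
    yp <- sample(c("blocker", "non_blocker"), 30, replace = TRUE)
    cm <- confusion(yt, yp)
    # enumeration oracle
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_along(yt)) {
      if (yt[i] == "blocker" && yp[i] == "blocker") tp <- tp + 1
      if (yt[i] != "blocker" && yp[i] == "blocker") fp <- fp + 1
      if (yt[i] != "blocker" && yp[i] != "blocker") tn <- tn + 1
      if (yt[i] == "blocker" && yp[i] != "blocker") fn <- fn + 1
    }
    expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 30)
  }
})

test_that("metrics follow their closed forms with undefined flags", {
  m <- classification_metrics(list(tp = 1, fp = 0, tn = 1, fn = 0))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  expect_warning(
    m0 <- classification_metrics(list(tp = 0, fp = 0, tn = 5, fn = 2)),
    "undefined"
  )
  expect_true(is.na(m0$precision))
  expect_true(m0$undefined[["precision"]])
  expect_equal(m0$accuracy, 5 / 7)

  # 43 correct of 50 gives 86.0% accuracy
  m43 <- classification_metrics(list(tp = 13, fp = 4, tn = 30, fn = 3))
  expect_equal(m43$accuracy, 0.86)

  # exhaustive closed-form sweep over small confusion tables
  for (tp in 0:3) for (fp in 0:3) for (tn in 0:3) for (fn in 0:3) {
    if (tp + fp + tn + fn == 0) next
    m <- suppressWarnings(
      classification_metrics(list(tp = tp, fp = fp, tn = tn, fn = fn))
    )
    expect_equal(m$accuracy, (tp + tn) / (tp + fp + tn + fn))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("AUC equals the pairwise concordance statistic", {
  y <- c("blocker", "blocker", "non_blocker", "non_blocker")
  expect_equal(roc_auc(y, c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(y, rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(y, c(0.9, 0.1, 0.8, 0.2)), 0.5)  # 2 of 4 pairs concordant

  set.seed(17)
  for (rep in 1:20) {
    yt <- sample(c("blocker", "non_blocker"), 25, replace = TRUE,
                 prob = c(0.4, 0.6))
    if (length(unique(yt)) < 2) next
    s <- round(stats::runif(25), 2)            # induce ties
    expect_equal(roc_auc(yt, s), oracle_auc(yt, s))
    # antisymmetry under score negation
    expect_equal(roc_auc(yt, -s), 1 - roc_auc(yt, s))
  }
  expect_error(roc_auc(rep("blocker", 3), 1:3), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  yt <- sample(c("blocker", "non_blocker"), 60, replace = TRUE)
  s <- stats::rnorm(60)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = yt, predictor = s, levels = c("non_blocker", "blocker"),
    direction = "<", quiet = TRUE
  )))
  expect_equal(roc_auc(yt, s), ref)
})

test_that("stratified folds partition with near-proportional classes", {
  labels <- rep(c("blocker", "non_blocker"), each = 20L)
  fold <- stratified_kfold(labels, k = 10L, seed = 3L)
  expect_equal(sort(unique(fold)), 1:10)
  for (f in 1:10) {
    expect_equal(sum(fold == f & labels == "blocker"), 2L)
    expect_equal(sum(fold == f & labels == "non_blocker"), 2L)
  }
  expect_identical(fold, stratified_kfold(labels, k = 10L, seed = 3L))
  expect_false(identical(fold, stratified_kfold(labels, k = 10L, seed = 4L)))

  # uneven class sizes: per-fold counts deviate from proportionality by <= 1
  labels2 <- c(rep("blocker", 23L), rep("non_blocker", 41L))
  fold2 <- stratified_kfold(labels2, k = 5L, seed = 1L)
  for (cl in unique(labels2)) {
    per <- table(fold2[labels2 == cl])
    expect_lte(max(per) - min(per), 1)
  }

  expect_error(stratified_kfold(c("blocker", rep("non_blocker", 20)), k = 5L),
               "at least k")
})

test_that("cross-validation conserves samples and aggregates folds", {
  spec <- synth_spec(n = 120L, seed = 41L)
  ds <- build_dataset(plant_activity(generate_molecules(spec), spec), "1-30")
  cv <- cross_validate(ds, model = "ecfp_svm", k = 3L, seed = 41L)
  expect_equal(nrow(cv$per_fold), 3L)
  expect_equal(sum(cv$per_fold$n), nrow(ds$records))
  expect_false(anyNA(cv$predictions$p_blocker))  # every sample predicted once
  for (m in c("accuracy", "f1", "auc")) {
    expect_gte(cv$mean[[m]], min(cv$per_fold[[m]]))
    expect_lte(cv$mean[[m]], max(cv$per_fold[[m]]))
  }
  expect_named(cv$pooled, c("accuracy", "precision", "recall", "f1", "auc"))
})

test_that("scheme comparison is a Welch t-test on fold metrics", {
  a <- c(0.8, 0.9, 0.7, 0.85)
  expect_equal(compare_schemes(a, a)$t, 0)
  cmp <- compare_schemes(a, a + 0.05)
  flipped <- compare_schemes(a + 0.05, a)
  expect_equal(cmp$t, -flipped$t)
  expect_equal(cmp$p_value, flipped$p_value)

  # closed-form Welch statistic
  b <- c(0.6, 0.65, 0.72, 0.58, 0.66)
  got <- compare_schemes(a, b)
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  expect_equal(got$t, (mean(a) - mean(b)) / se)
})

test_that("leverage reproduces hand computations and the trace identity", {
  expect_equal(leverage(diag(2))$h, c(1, 1))
  expect_equal(leverage(diag(2), c(0, 0))$h, 0)

  X <- rbind(c(1, 0), c(1, 1), c(1, 2))
  rep_ <- leverage(X, c(1, 0))
  expect_equal(rep_$h, 5 / 6)
  expect_equal(rep_$threshold, 3 * 2 / 3)
  expect_equal(sum(leverage(X)$h), 2)          # trace identity: rank(X) = D

  set.seed(23)
  for (rep in 1:10) {
    Xr <- matrix(stats::rnorm(60), 12, 5)
    expect_equal(sum(leverage(Xr)$h), 5, tolerance = 1e-8)
    expect_true(all(leverage(Xr)$h >= 0 & leverage(Xr)$h <= 1 + 1e-12))
  }

  # rank-deficient latent covariance engages the pseudo-inverse
  Xd <- cbind(1:4, (1:4) * 2)
  rd <- leverage(Xd)
  expect_true(rd$used_pseudoinverse)
  expect_equal(sum(rd$h), 1, tolerance = 1e-8)  # rank 1
})
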