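# Model-level behaviour: training, prediction, reproducibility,
# interpretation, serialization.

fit_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- gstn(toy_separable(), epochs = 60L, seed = 11L)
    }
    cache
  }
})

test_that("probabilities are normalized and deterministic", {
  fit <- fit_toy()
  mol <- parse_molecule("c1ccc(NC)cc1")
  g <- build_graph(mol)
  tens <- build_subgraph_tensor(g, mol)
  p <- gstn_forward(fit, g, tens)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_identical(p, gstn_forward(fit, g, tens))   # same params, same output

  # predict() on the canonical spelling agrees with the explicit forward
  expect_equal(unname(predict(fit, "c1ccc(NC)cc1")), unname(p[["blocker"]]))
})

test_that("predictions are invariant to SMILES spelling", {
  fit <- fit_toy()
  smiles <- c("c1ccc(N(C)C)cc1", "c1ccc(C(F)(F)F)cc1", "CSc1ccc(CN)cc1")
  variants <- randomized_smiles(smiles, n = 8L, seed = 3L)
  for (i in seq_along(smiles)) {
    p <- vapply(c(smiles[i], variants[[i]]),
                function(s) predict(fit, s), numeric(1))
    expect_true(all(p == p[1]))
  }
})

test_that("training separates a separable toy set and is seed-reproducible", {
  fit <- fit_toy()
  toy <- toy_separable()
  expect_equal(mean(predict(fit, toy$smiles, type = "class") == toy$label), 1)
  # loss trends downward
  expect_lt(utils::tail(fit$loss_history, 1), fit$loss_history[1])

  fit2 <- gstn(toy_separable(), epochs = 60L, seed = 11L)
  expect_identical(fit$params, fit2$params)

  one_class <- toy[toy$label == "blocker", ]
  expect_error(gstn(one_class, epochs = 1L), "both classes")
})

test_that("attention shares are a probability vector over kinds", {
  fit <- fit_toy()
  shares <- subgraph_weight_shares(fit)
  expect_named(shares, subgraph_kinds())
  expect_equal(sum(shares), 1, tolerance = 1e-9)
  expect_true(all(shares >= 0))

  # averaging over fold models stays normalized
  fit2 <- gstn(toy_separable(), epochs = 5L, seed = 2L)
  shares2 <- subgraph_weight_shares(fit, over_folds = list(fit2))
  expect_equal(sum(shares2), 1, tolerance = 1e-9)

  single <- gstn(toy_separable(), kinds = "all_atoms", epochs = 5L, seed = 2L)
  expect_equal(unname(subgraph_weight_shares(single)), 1)

  cf <- coef(fit)
  expect_equal(dim(cf), c(2L, 4L))
  expect_equal(unname(rowSums(cf)), c(1, 1), tolerance = 1e-9)
})

test_that("interpretation matrices reproduce the forward-pass meta-paths", {
  fit <- fit_toy()
  # a molecule from the printed activity-cliff case studies
  smi <- load_fixture("scaffold_cases")$smiles[17]
  bundle <- interpretation_matrices(fit, smi)
  n_max <- fit$config$n_max
  expect_length(bundle$G, 4L)
  for (G in bundle$G) expect_equal(dim(G), c(n_max, n_max))
  expect_length(bundle$Q, fit$config$n_heads)
  expect_equal(bundle$Q_p, bundle$Q[[1]] %*% bundle$Q[[2]])

  # Q_k recomputed from the shares equals the export
  W <- coef(fit)
  mol <- parse_molecule(smi)
  tens <- build_subgraph_tensor(build_graph(mol), mol, fit$kinds)
  expect_equal(bundle$Q[[1]], meta_path(tens, W[1, ]))
})

test_that("latent fingerprints have dimension 64 and ignore padding", {
  fit <- fit_toy()
  lat <- latent_features(fit, c("c1ccc(N)cc1", "c1ccc(N)cc1", "c1ccc(C)cc1"))
  expect_equal(ncol(lat), 64L)
  expect_identical(lat[1, ], lat[2, ])     # identical molecules, identical vectors
  expect_false(all(lat[1, ] == lat[3, ]))

  # growing the pad size leaves the latent vector unchanged
  fit_pad <- fit
  fit_pad$config$n_max <- 60L
  # head weights are tied to n_max * d, so compare through the graph stage
  mol <- parse_molecule("c1ccc(N)cc1")
  inp <- gstn:::prepare_mol_input(mol, fit$kinds, n_max = 45L)
  cache45 <- gstn:::gstn_graph_stage(inp, fit$params, fit$config)
  inp60 <- gstn:::prepare_mol_input(mol, fit$kinds, n_max = 60L)
  cache60 <- gstn:::gstn_graph_stage(inp60, fit$params, fit_pad$config)
  expect_identical(colMeans(cache45$latent), colMeans(cache60$latent))
})

test_that("model archives reload to bit-identical predictions", {
  fit <- fit_toy()
  path <- tempfile(fileext = ".json")
  save_gstn(fit, path)
  fit2 <- load_gstn(path)
  smiles <- toy_separable()$smiles
  expect_identical(predict(fit, smiles), predict(fit2, smiles))
  expect_identical(fit$params, fit2$params)
  expect_error(load_gstn(system.file("extdata", "fda50.tsv",
                                     package = "gstn")))
  unlink(path)
})

test_that("planted-rule benchmark is learnable at a modest size", {
  spec <- synth_spec(n = 240L, seed = 31L)
  bench <- make_benchmark(spec)
  ds <- build_dataset(bench$records, "1-30")
  fold <- stratified_kfold(ds$records$label, k = 4L, seed = 31L)
  train <- ds$records[fold != 1L, ]
  test <- ds$records[fold == 1L, ]
  fit <- gstn(train, epochs = 40L, seed = 31L)
  acc <- mean(predict(fit, test$smiles, type = "class") == test$label)
  expect_gt(acc, 0.85)
})
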