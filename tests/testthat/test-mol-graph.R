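test_that("SMILES parsing yields canonical molecules", {
  mol <- parse_molecule("CCO")
  expect_equal(mol$n_heavy, 3L)
  expect_equal(nrow(mol$bonds), 2L)
  expect_true("O" %in% mol$atoms$element)

  benz <- parse_molecule("c1ccccc1")
  expect_equal(benz$n_heavy, 6L)
  expect_true(all(benz$atoms$aromatic))
  expect_equal(nrow(benz$bonds), 6L)
  expect_true(all(benz$bonds$aromatic))

  expect_error(parse_molecule("C("), "parse error")
  expect_error(parse_molecule("   "), "parse error")

  # printed-table strings with typographic spaces parse after sanitization
  spaced <- parse_molecule("OC(=O)c1ccc(cc1)C2 = CC3(CCNCC3)Oc4ccccc24")
  expect_equal(spaced$canonical_smiles,
               canonical_smiles("OC(=O)c1ccc(cc1)C2=CC3(CCNCC3)Oc4ccccc24"))
})

test_that("padded graphs satisfy the adjacency contract", {
  mol <- parse_molecule("CCO")
  g <- build_graph(mol)
  expect_equal(dim(g$A), c(45L, 45L))
  expect_equal(sum(g$A != 0), 4L)              # 2 bonds x symmetry
  expect_equal(g$A, t(g$A))
  expect_true(all(diag(g$A) == 0))
  expect_true(all(g$A[4:45, ] == 0))           # padding rows empty
  expect_true(all(g$X[4:45, ] == 0))

  for (smi in c("c1ccccc1", "CC(=O)Nc1ccc(O)cc1", "C1CCNCC1")) {
    m <- parse_molecule(smi)
    expect_equal(sum(build_graph(m)$A), 2 * nrow(m$bonds))
  }

  big <- parse_molecule(strrep("C", 50))
  expect_error(build_graph(big), "fewer than 45")
})

test_that("Murcko scaffolds match printed references and are idempotent", {
  m1 <- parse_molecule("OC(=O)c1ccc(cc1)C2=CC3(CCNCC3)Oc4ccccc24")
  s1 <- murcko_scaffold(m1)
  expect_equal(s1$smiles, canonical_smiles("C1=C(c2ccccc2)c2ccccc2OC12CCNCC2"))
  expect_gt(length(s1$atoms), 0L)

  m2 <- parse_molecule("CN(C)CCCCc1ccc(cc1)C2(C)COC2")
  expect_equal(murcko_scaffold(m2)$smiles,
               canonical_smiles("c1ccc(C2COC2)cc1"))

  # acyclic molecules have an empty scaffold, not an error
  eth <- murcko_scaffold(parse_molecule("CCO"))
  expect_length(eth$atoms, 0L)
  expect_equal(eth$smiles, "")

  # idempotence: the scaffold of a scaffold is itself
  for (smi in c("c1ccc(Oc2ccccc2)cc1", "O=C(c1ccccc1)N1CCC(Cc2ccccc2)CC1")) {
    sc <- murcko_scaffold(parse_molecule(smi))$smiles
    expect_equal(murcko_scaffold(parse_molecule(sc))$smiles, sc)
  }
})

test_that("aromatic and heteroatom sets follow perception", {
  expect_length(aromatic_ring_atoms(parse_molecule("c1ccccc1")), 6L)
  expect_length(aromatic_ring_atoms(parse_molecule("CCO")), 0L)
  # pyridine: the ring nitrogen is aromatic and included
  pyr <- parse_molecule("c1ccncc1")
  expect_length(aromatic_ring_atoms(pyr), 6L)
  expect_true(which(pyr$atoms$element == "N") %in% aromatic_ring_atoms(pyr))

  eth <- parse_molecule("CCO")
  expect_equal(heteroatom_set(eth), which(eth$atoms$element == "O"))
  expect_length(heteroatom_set(parse_molecule("c1ccccc1")), 0L)
  css <- parse_molecule("CSC")
  expect_equal(css$atoms$element[heteroatom_set(css)], "S")
  # halogens and phosphorus are not N/O/S heteroatoms
  expect_length(heteroatom_set(parse_molecule("FC(F)(F)Cl")), 0L)
})

test_that("sub-adjacency extraction honors induced and incident modes", {
  mol <- parse_molecule("CCO")
  A <- build_graph(mol, n_max = 4L)$A
  all_idx <- seq_len(4L)
  expect_equal(subgraph_adjacency(A, all_idx, "induced"), A)
  expect_equal(subgraph_adjacency(A, all_idx, "incident"), A)
  expect_equal(subgraph_adjacency(A, integer(0), "induced"), A * 0)
  expect_equal(subgraph_adjacency(A, integer(0), "incident"), A * 0)

  # ethanol, atoms = {O}: incident keeps exactly the C-O bond
  o_idx <- heteroatom_set(mol)
  inc <- subgraph_adjacency(A, o_idx, "incident")
  expect_equal(sum(inc), 2)                       # one symmetric edge
  expect_equal(subgraph_adjacency(A, o_idx, "induced"), A * 0)

  expect_error(subgraph_adjacency(A, 5L), "out of range")

  # induced is always entrywise <= incident <= A
  set.seed(11)
  m <- parse_molecule("CC(=O)Nc1ccc(O)cc1")
  Am <- build_graph(m, n_max = m$n_heavy + 1L)$A
  atoms <- sample(seq_len(m$n_heavy), 4L)
  ind <- subgraph_adjacency(Am, atoms, "induced")
  inc <- subgraph_adjacency(Am, atoms, "incident")
  expect_true(all(ind <= inc))
  expect_true(all(inc <= Am))
})

test_that("subgraph tensors stack slices in the fixed order", {
  mol <- parse_molecule("CC(=O)Nc1ccc(O)cc1")
  g <- build_graph(mol)
  tens <- build_subgraph_tensor(g, mol)
  expect_equal(dim(tens$M), c(4L, 45L, 45L))
  expect_equal(tens$M[1, , ], g$A)                # all_atoms slice equals A
  for (t in 1:4) {
    G <- tens$M[t, , ]
    expect_equal(G, t(G))
    expect_true(all(G >= 0 & G <= g$A))
    expect_true(all(diag(G) == 0))
  }

  single <- build_subgraph_tensor(g, mol, "all_atoms")
  expect_equal(dim(single$M), c(1L, 45L, 45L))

  # acyclic molecule: murcko slice is all zero
  eth <- parse_molecule("CCO")
  ge <- build_graph(eth)
  te <- build_subgraph_tensor(ge, eth, c("all_atoms", "murcko"))
  expect_true(all(te$M[2, , ] == 0))

  expect_error(build_subgraph_tensor(g, mol, "rings_of_power"), "unknown")
  expect_error(build_subgraph_tensor(g, mol, c("murcko", "all_atoms")),
               "order")
})

test_that("different spellings of a structure give identical A, X and M", {
  smiles <- c("CC(=O)Nc1ccc(O)cc1", "c1ccc2ccccc2c1", "CSc1ccc(CN)cc1",
              "O=C(c1ccccc1)N1CCC(Cc2ccccc2)CC1", "C1CC2(CCN1)Oc3ccccc3C(=C2)c4ccccc4")
  variants <- randomized_smiles(smiles, n = 5L, seed = 99L)
  for (i in seq_along(smiles)) {
    ref_mol <- parse_molecule(smiles[i])
    ref_g <- build_graph(ref_mol)
    ref_t <- build_subgraph_tensor(ref_g, ref_mol)
    for (alt in variants[[i]]) {
      mol <- parse_molecule(alt)
      g <- build_graph(mol)
      expect_identical(g$A, ref_g$A)
      expect_identical(g$X, ref_g$X)
      expect_identical(build_subgraph_tensor(g, mol)$M, ref_t$M)
    }
  }
})

test_that("every scaffold_cases row reproduces the printed Murcko column", {
  sc <- load_fixture("scaffold_cases")
  mols <- parse_molecules(sc$smiles, on_error = "stop")
  got <- vapply(mols, function(m) m$murcko_smiles, character(1))
  want <- canonical_smiles(sc$murcko)
  expect_identical(got, want)
})
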