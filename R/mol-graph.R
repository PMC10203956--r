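# Molecular graphs, predefined subgraphs, and the subgraph tensor.

#' Predefined subgraph kinds
#'
#' The fixed, ordered enumeration of predefined subgraphs: the whole
#' molecule, the Murcko scaffold (ring systems plus linkers), the aromatic
#' rings, and the heteroatom (N/O/S) edges. The order is part of the model
#' contract: tensors and learned weights are always indexed in this order.
#'
#' @return character vector of the four kind names.
#' @export
subgraph_kinds <- function() {
  c("all_atoms", "murcko", "aromatic_rings", "heteroatoms")
}

# element channels of the atom-feature layout; anything else maps to "other"
.feature_elements <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")

#' Atom feature dimensionality
#'
#' The fixed atom-feature layout is: one-hot element over
#' \{C, N, O, S, F, Cl, Br, I, P, other\} (10), one-hot degree 0-5 (6),
#' aromatic flag, in-ring flag, and signed formal charge; 19 channels in
#' total.
#'
#' @return integer, the number of feature channels.
#' @export
feature_dim <- function() length(.feature_elements) + 1L + 6L + 3L

#' Atom feature matrix
#'
#' @param mol a `gstn_molecule`.
#' @return numeric matrix `n_heavy x feature_dim()` following the layout
#'   documented in [feature_dim()].
#' @export
atom_features <- function(mol) {
  stopifnot(inherits(mol, "gstn_molecule"))
  n <- mol$n_heavy
  X <- matrix(0, nrow = n, ncol = feature_dim())
  el <- match(mol$atoms$element, .feature_elements)
  el[is.na(el)] <- length(.feature_elements) + 1L
  X[cbind(seq_len(n), el)] <- 1
  off <- length(.feature_elements) + 1L
  deg <- pmin(mol$atoms$degree, 5L)
  X[cbind(seq_len(n), off + 1L + deg)] <- 1
  X[, off + 7L] <- as.numeric(mol$atoms$aromatic)
  X[, off + 8L] <- as.numeric(mol$atoms$in_ring)
  X[, off + 9L] <- mol$atoms$charge
  X
}

#' Build a padded molecular graph
#'
#' Constructs the binary adjacency matrix `A` and atom-feature matrix `X`,
#' zero-padded to a fixed size so that all molecules share one tensor
#' shape. Molecules with `n_heavy >= n_max` are rejected: the corpus is
#' restricted to molecules with fewer than 45 non-hydrogen atoms.
#'
#' @param mol a `gstn_molecule` from [parse_molecule()].
#' @param n_max padded size (default 45).
#' @return an object of class `gstn_graph` with components `A`
#'   (`n_max x n_max`, symmetric, zero diagonal), `X`
#'   (`n_max x feature_dim()`), `n_real` and `n_max`.
#' @export
build_graph <- function(mol, n_max = 45L) {
  stopifnot(inherits(mol, "gstn_molecule"))
  if (mol$n_heavy >= n_max) {
    stop("molecule has ", mol$n_heavy, " heavy atoms; only molecules with ",
         "fewer than ", n_max, " non-hydrogen atoms are accepted ",
         "(size filter)", call. = FALSE)
  }
  A <- matrix(0, n_max, n_max)
  if (nrow(mol$bonds)) {
    A[cbind(mol$bonds$i, mol$bonds$j)] <- 1
    A[cbind(mol$bonds$j, mol$bonds$i)] <- 1
  }
  X <- matrix(0, n_max, feature_dim())
  X[seq_len(mol$n_heavy), ] <- atom_features(mol)
  structure(list(A = A, X = X, n_real = mol$n_heavy, n_max = as.integer(n_max)),
            class = "gstn_graph")
}

#' @export
print.gstn_graph <- function(x, ...) {
  cat("<molecular graph> ", x$n_real, " real atoms padded to ", x$n_max,
      "; ", sum(x$A) / 2, " bonds\n", sep = "")
  invisible(x)
}

#' Murcko scaffold of a molecule
#'
#' The Murcko scaffold is the union of a molecule's ring systems and the
#' linker atoms connecting them. Acyclic molecules have an empty scaffold,
#' which is not an error.
#'
#' @param mol a `gstn_molecule`.
#' @return list with `atoms` (1-based indices into the canonical atom
#'   order; empty for acyclic molecules) and `smiles` (canonical scaffold
#'   SMILES, `""` if empty).
#' @export
murcko_scaffold <- function(mol) {
  stopifnot(inherits(mol, "gstn_molecule"))
  list(atoms = mol$murcko_atoms, smiles = mol$murcko_smiles)
}

#' Aromatic ring atoms
#'
#' @param mol a `gstn_molecule`.
#' @return 1-based indices of all atoms flagged aromatic by the perception
#'   backend.
#' @export
aromatic_ring_atoms <- function(mol) {
  stopifnot(inherits(mol, "gstn_molecule"))
  mol$aromatic_atoms
}

#' Heteroatom set
#'
#' Nitrogen, oxygen and sulfur atoms (aromatic or not); other elements are
#' excluded.
#'
#' @param mol a `gstn_molecule`.
#' @return 1-based atom indices.
#' @export
heteroatom_set <- function(mol) {
  stopifnot(inherits(mol, "gstn_molecule"))
  which(mol$atoms$element %in% c("N", "O", "S"))
}

#' Sub-adjacency matrix for an atom set
#'
#' `induced` keeps an edge iff both endpoints are in `atoms`; `incident`
#' keeps an edge iff at least one endpoint is. The result is symmetric,
#' binary and entrywise bounded by `A`.
#'
#' @param A adjacency matrix.
#' @param atoms 1-based atom indices.
#' @param mode `"induced"` or `"incident"`.
#' @return matrix of the same shape as `A`.
#' @export
subgraph_adjacency <- function(A, atoms, mode = c("induced", "incident")) {
  mode <- match.arg(mode)
  n <- nrow(A)
  atoms <- as.integer(atoms)
  if (length(atoms) && (min(atoms) < 1L || max(atoms) > n)) {
    stop("atom index out of range [1, ", n, "]", call. = FALSE)
  }
  ind <- rep(0, n)
  ind[atoms] <- 1
  mask <- if (mode == "induced") outer(ind, ind) else 1 - outer(1 - ind, 1 - ind)
  A * mask
}

#' Build the subgraph tensor
#'
#' Stacks the sub-adjacency matrices of the requested subgraph kinds into a
#' tensor `M` of shape `T x n_max x n_max`. The `all_atoms` slice equals
#' `A`; `murcko` and `aromatic_rings` use induced edges (both endpoints
#' inside the substructure); `heteroatoms` uses incident edges (any edge
#' touching an N/O/S atom), since N/O/S atoms are rarely bonded to each
#' other and an induced heteroatom subgraph would carry no message-passing
#' signal. Slices carry no self-loops; the identity is added once inside
#' [normalize_propagator()].
#'
#' @param graph a `gstn_graph`.
#' @param mol the `gstn_molecule` the graph was built from.
#' @param kinds subset of [subgraph_kinds()], in enumeration order.
#' @return an object of class `gstn_tensor`: list with `M` (3-D array),
#'   `kinds`, `n_real`, `n_max`.
#' @export
build_subgraph_tensor <- function(graph, mol, kinds = subgraph_kinds()) {
  stopifnot(inherits(graph, "gstn_graph"), inherits(mol, "gstn_molecule"))
  all_kinds <- subgraph_kinds()
  if (!length(kinds) || !all(kinds %in% all_kinds)) {
    stop("unknown subgraph kind: ",
         paste(setdiff(kinds, all_kinds), collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(match(kinds, all_kinds), strictly = TRUE)) {
    stop("kinds must follow the fixed enumeration order: ",
         paste(all_kinds, collapse = ", "), call. = FALSE)
  }
  slices <- lapply(kinds, function(kind) {
    switch(kind,
      all_atoms = graph$A,
      murcko = subgraph_adjacency(graph$A, mol$murcko_atoms, "induced"),
      aromatic_rings = subgraph_adjacency(graph$A, mol$aromatic_atoms, "induced"),
      heteroatoms = subgraph_adjacency(graph$A, heteroatom_set(mol), "incident")
    )
  })
  M <- array(0, dim = c(length(kinds), graph$n_max, graph$n_max),
             dimnames = list(kinds, NULL, NULL))
  for (t in seq_along(slices)) M[t, , ] <- slices[[t]]
  structure(list(M = M, kinds = kinds, n_real = graph$n_real,
                 n_max = graph$n_max),
            class = "gstn_tensor")
}

#' @export
print.gstn_tensor <- function(x, ...) {
  cat("<subgraph tensor> T = ", length(x$kinds), " (",
      paste(x$kinds, collapse = ", "), "), ", x$n_max, " x ", x$n_max,
      "\n", sep = "")
  invisible(x)
}

# Compact per-molecule input for model fitting: unpadded feature matrix and
# subgraph slices restricted to the real atoms. Padded nodes contribute
# all-zero latent rows (the identity self-loop maps zero features to zero),
# so working at n_real size is exact and much faster.
prepare_mol_input <- function(mol, kinds, n_max = 45L) {
  n <- mol$n_heavy
  if (n >= n_max) {
    stop("molecule has ", n, " heavy atoms; the size filter admits fewer ",
         "than ", n_max, call. = FALSE)
  }
  A <- matrix(0, n, n)
  if (nrow(mol$bonds)) {
    A[cbind(mol$bonds$i, mol$bonds$j)] <- 1
    A[cbind(mol$bonds$j, mol$bonds$i)] <- 1
  }
  G <- lapply(kinds, function(kind) {
    switch(kind,
      all_atoms = A,
      murcko = subgraph_adjacency(A, mol$murcko_atoms, "induced"),
      aromatic_rings = subgraph_adjacency(A, mol$aromatic_atoms, "induced"),
      heteroatoms = subgraph_adjacency(A, heteroatom_set(mol), "incident")
    )
  })
  list(n = n, X = atom_features(mol), G = G)
}
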