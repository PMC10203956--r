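# Bridge to the bundled RDKit helper (inst/python/chem_backend.py).
# All calls are batched: one subprocess per request, JSON in/out, and the
# per-structure results are memoised so repeated parsing is free.

.chem_cache <- new.env(parent = emptyenv())

chem_python <- function() {
  opt <- getOption("gstn.python", NULL)
  if (!is.null(opt)) return(opt)
  for (cand in c("python3", "python")) {
    path <- Sys.which(cand)
    if (nzchar(path)) return(path)
  }
  stop("no python interpreter found on PATH; the chemistry backend needs ",
       "python with the rdkit package", call. = FALSE)
}

chem_backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "gstn")
  if (!nzchar(path)) stop("chem_backend.py not found in the installed package")
  path
}

chem_backend_call <- function(op, payload = list()) {
  req <- c(list(op = op), payload)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(req, fin, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(chem_python(), c(chem_backend_script(), fin, fout),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("chemistry backend call failed (op = ", op, ")", call. = FALSE)
  }
  jsonlite::read_json(fout)
}

#' Strip whitespace from SMILES strings
#'
#' Printed activity tables sometimes contain typographic spaces inside the
#' SMILES (e.g. `"C2 = CC3"`); they are removed before parsing.
#'
#' @param smiles character vector.
#' @return character vector with all whitespace removed.
#' @export
sanitize_smiles <- function(smiles) {
  gsub("[[:space:]]+", "", smiles)
}

cache_key <- function(prefix, x) paste0(prefix, "\r", x)

# batch-fetch mol_info for all uncached structures, then return the cached
# entries in input order (NULL entries mark parse failures)
mol_info_batch <- function(smiles) {
  smiles <- sanitize_smiles(smiles)
  keys <- cache_key("info", smiles)
  missing <- !vapply(keys, exists, logical(1), envir = .chem_cache)
  todo <- unique(smiles[missing])
  if (length(todo)) {
    res <- chem_backend_call("mol_info", list(smiles = I(todo)))
    for (i in seq_along(todo)) {
      entry <- res[[i]]
      assign(cache_key("info", todo[i]),
             if (!is.null(entry$error)) NULL else entry,
             envir = .chem_cache)
    }
  }
  lapply(keys, function(k) get0(k, envir = .chem_cache))
}

#' Parse SMILES into molecules
#'
#' Parses one or more SMILES strings with the RDKit backend. Each structure
#' is reduced to its largest fragment, stripped of stereochemistry, and
#' renumbered into the backend's canonical atom ranking, so that two
#' spellings of the same structure yield identical atom indexing. Hydrogens
#' are implicit and never counted.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `gstn_molecule` with components
#'   `canonical_smiles`, `n_heavy`, `atoms` (data frame: `element`,
#'   `aromatic`, `charge`, `in_ring`, `degree`), `bonds` (data frame with
#'   1-based atom indices `i`, `j` and an `aromatic` flag), `murcko_atoms`
#'   (1-based indices of the Murcko scaffold), `murcko_smiles` (canonical
#'   scaffold SMILES, `""` for acyclic molecules) and `aromatic_atoms`.
#' @examples
#' \dontrun{
#' mol <- parse_molecule("CCO")
#' mol$n_heavy  # 3
#' }
#' @seealso [parse_molecules()] for the batched form.
#' @export
parse_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(sanitize_smiles(smiles))) {
    stop("SMILES parse error: empty input", call. = FALSE)
  }
  mols <- parse_molecules(smiles)
  if (is.null(mols[[1]])) {
    stop("SMILES parse error: ", dQuote(smiles), call. = FALSE)
  }
  mols[[1]]
}

#' @rdname parse_molecule
#' @param on_error `"null"` returns `NULL` for unparseable entries, `"stop"`
#'   raises an error naming the offending inputs.
#' @return for `parse_molecules`, a list of `gstn_molecule` objects (or
#'   `NULL` entries when `on_error = "null"`).
#' @export
parse_molecules <- function(smiles, on_error = c("null", "stop")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles))
  infos <- mol_info_batch(smiles)
  bad <- vapply(infos, is.null, logical(1))
  if (on_error == "stop" && any(bad)) {
    stop("SMILES parse error: ",
         paste(dQuote(utils::head(smiles[bad], 5L)), collapse = ", "),
         if (sum(bad) > 5L) " ..." else "", call. = FALSE)
  }
  lapply(infos, function(info) {
    if (is.null(info)) return(NULL)
    as_molecule(info)
  })
}

as_molecule <- function(info) {
  atoms <- data.frame(
    element = vapply(info$atoms, `[[`, character(1), "element"),
    aromatic = vapply(info$atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(info$atoms, function(a) as.integer(a$charge), integer(1)),
    in_ring = vapply(info$atoms, `[[`, logical(1), "in_ring"),
    degree = vapply(info$atoms, function(a) as.integer(a$degree), integer(1)),
    stringsAsFactors = FALSE
  )
  if (length(info$bonds)) {
    bm <- do.call(rbind, lapply(info$bonds, function(b) {
      c(as.integer(b[[1]]) + 1L, as.integer(b[[2]]) + 1L, as.integer(b[[3]]))
    }))
    bonds <- data.frame(i = bm[, 1], j = bm[, 2], aromatic = bm[, 3] == 1L)
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), aromatic = logical(0))
  }
  structure(
    list(
      canonical_smiles = info$canonical_smiles,
      n_heavy = as.integer(info$n_heavy),
      atoms = atoms,
      bonds = bonds,
      murcko_atoms = as.integer(unlist(info$murcko_atoms)) + 1L,
      murcko_smiles = info$murcko_smiles,
      aromatic_atoms = as.integer(unlist(info$aromatic_atoms)) + 1L
    ),
    class = "gstn_molecule"
  )
}

#' @export
print.gstn_molecule <- function(x, ...) {
  cat("<molecule> ", x$canonical_smiles, "\n", sep = "")
  cat("  heavy atoms: ", x$n_heavy, ", bonds: ", nrow(x$bonds), "\n", sep = "")
  if (nzchar(x$murcko_smiles)) {
    cat("  Murcko scaffold: ", x$murcko_smiles, "\n", sep = "")
  } else {
    cat("  Murcko scaffold: none (acyclic)\n")
  }
  invisible(x)
}

#' Canonical SMILES
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of backend-canonical SMILES; `NA` for
#'   unparseable inputs.
#' @export
canonical_smiles <- function(smiles) {
  res <- chem_backend_call("canonical", list(smiles = I(sanitize_smiles(smiles))))
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

#' Randomized SMILES spellings
#'
#' Generates alternative, randomly ordered SMILES spellings of the same
#' structures; used to exercise canonicalization invariance.
#'
#' @param smiles character vector.
#' @param n number of spellings per structure.
#' @param seed integer seed for the backend generator.
#' @return list of character vectors, one per input.
#' @export
randomized_smiles <- function(smiles, n = 10L, seed = 1L) {
  res <- chem_backend_call(
    "random_smiles",
    list(smiles = I(sanitize_smiles(smiles)), n = n, seed = seed)
  )
  lapply(res, function(x) {
    if (!is.null(x$error)) stop("SMILES parse error in randomized_smiles")
    unlist(x$smiles)
  })
}

#' Extended-connectivity (circular) fingerprints
#'
#' Hashed Morgan fingerprints; `diameter = 4` corresponds to the usual
#' ECFP4 (Morgan radius 2).
#'
#' @param smiles character vector of SMILES strings.
#' @param n_bits fingerprint length.
#' @param diameter circular diameter (radius is `diameter / 2`).
#' @return binary integer matrix, one row per molecule, `n_bits` columns.
#' @export
ecfp <- function(smiles, n_bits = 1024L, diameter = 4L) {
  stopifnot(diameter %% 2 == 0)
  smiles <- sanitize_smiles(smiles)
  key <- cache_key(sprintf("ecfp%d.%d", n_bits, diameter), smiles)
  missing <- !vapply(key, exists, logical(1), envir = .chem_cache)
  todo <- unique(smiles[missing])
  if (length(todo)) {
    res <- chem_backend_call(
      "ecfp",
      list(smiles = I(todo), n_bits = n_bits, radius = diameter / 2L)
    )
    for (i in seq_along(todo)) {
      entry <- res[[i]]
      if (!is.null(entry$error)) {
        stop("SMILES parse error: ", dQuote(todo[i]), call. = FALSE)
      }
      assign(cache_key(sprintf("ecfp%d.%d", n_bits, diameter), todo[i]),
             as.integer(unlist(entry$bits)), envir = .chem_cache)
    }
  }
  out <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  for (i in seq_along(smiles)) {
    bits <- get(key[i], envir = .chem_cache)
    out[i, bits + 1L] <- 1L
  }
  rownames(out) <- names(smiles)
  out
}
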