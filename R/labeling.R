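# IC50 thresholding schemes and labeled dataset construction.

#' Threshold schemes for IC50 labeling
#'
#' A scheme is a pair of cutoffs in micromolar: molecules with
#' `IC50 <= active_thr_um` are blockers, molecules with
#' `IC50 > inactive_thr_um` are non-blockers, and everything in between is
#' undefined ("weak blockers") and removed from a labeled dataset. With
#' `active_thr_um == inactive_thr_um` the scheme is a single threshold and
#' no molecule is undefined. The boundary semantics follow the usual
#' "<= active / > inactive" convention, so an IC50 exactly at the inactive
#' cutoff of a dual scheme is undefined.
#'
#' Named schemes: `"1"`, `"10"`, `"20"` (single) and `"1-10"`, `"1-20"`,
#' `"1-30"`, `"1-40"` (dual; `"[1,30]"`-style names are also accepted).
#' `"1-30"` is the recommended default.
#'
#' @param active_thr_um active (blocker) threshold in uM, or a scheme name.
#' @param inactive_thr_um inactive (non-blocker) threshold in uM; defaults
#'   to `active_thr_um` (single threshold).
#' @return an object of class `gstn_scheme`.
#' @examples
#' \dontrun{
#' threshold_scheme("1-30")
#' threshold_scheme(1, 10)
#' }
#' @export
threshold_scheme <- function(active_thr_um = 1, inactive_thr_um = NULL) {
  if (is.character(active_thr_um)) {
    name <- gsub("[][ ]", "", active_thr_um)
    parts <- strsplit(name, "[-,]")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)) || !length(vals) %in% 1:2) {
      stop("unknown threshold scheme name: ", dQuote(active_thr_um),
           "; use e.g. \"1\", \"10\", \"20\", \"1-10\", \"1-20\", ",
           "\"1-30\", \"1-40\"", call. = FALSE)
    }
    active_thr_um <- vals[1]
    inactive_thr_um <- if (length(vals) == 2L) vals[2] else vals[1]
  }
  if (is.null(inactive_thr_um)) inactive_thr_um <- active_thr_um
  stopifnot(is.numeric(active_thr_um), is.numeric(inactive_thr_um),
            active_thr_um > 0, inactive_thr_um > 0)
  if (active_thr_um > inactive_thr_um) {
    stop("active threshold must not exceed the inactive threshold",
         call. = FALSE)
  }
  structure(
    list(
      active_thr_um = active_thr_um,
      inactive_thr_um = inactive_thr_um,
      single = active_thr_um == inactive_thr_um,
      name = if (active_thr_um == inactive_thr_um) {
        format(active_thr_um)
      } else {
        paste0("[", format(active_thr_um), ",", format(inactive_thr_um), "]")
      }
    ),
    class = "gstn_scheme"
  )
}

#' @export
print.gstn_scheme <- function(x, ...) {
  if (x$single) {
    cat("<threshold scheme> single: <=", x$active_thr_um, "uM blocker, >",
        x$active_thr_um, "uM non-blocker\n")
  } else {
    cat("<threshold scheme> dual: <=", x$active_thr_um, "uM blocker, >",
        x$inactive_thr_um, "uM non-blocker, in between removed\n")
  }
  invisible(x)
}

#' Assign blocker / non-blocker labels
#'
#' @param ic50_um positive IC50 values in micromolar (vectorized).
#' @param scheme a `gstn_scheme` or scheme name.
#' @return character vector in `{"blocker", "non_blocker", "undefined"}`.
#' @export
assign_label <- function(ic50_um, scheme) {
  if (!inherits(scheme, "gstn_scheme")) scheme <- threshold_scheme(scheme)
  ic50_um <- as.numeric(ic50_um)
  if (any(is.na(ic50_um)) || any(ic50_um <= 0)) {
    stop("IC50 values must be positive and non-missing", call. = FALSE)
  }
  out <- rep("undefined", length(ic50_um))
  out[ic50_um <= scheme$active_thr_um] <- "blocker"
  out[ic50_um > scheme$inactive_thr_um] <- "non_blocker"
  out
}

#' Read an activity table
#'
#' Comma- or tab-delimited text with a header row and columns `id`,
#' `smiles`, `ic50_um`.
#'
#' @param path file path.
#' @return data frame with columns `id`, `smiles`, `ic50_um`.
#' @export
read_activity_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("id", "smiles", "ic50_um")
  if (!all(need %in% names(df))) {
    stop("activity table must have header columns ",
         paste(need, collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  df$id <- as.character(df$id)
  df$smiles <- as.character(df$smiles)
  df$ic50_um <- as.numeric(df$ic50_um)
  bad <- which(is.na(df$ic50_um) | df$ic50_um <= 0)
  if (length(bad)) {
    stop("non-positive or missing ic50_um in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' Build a labeled blocker / non-blocker dataset
#'
#' Applies a thresholding scheme to activity records, removes undefined
#' ("weak blocker") records, enforces the 45-heavy-atom size filter, and
#' optionally balances the classes by uniform seed-controlled subsampling
#' of the majority class (no oversampling).
#'
#' @param records data frame with columns `id`, `smiles`, `ic50_um` (or a
#'   path readable by [read_activity_table()]).
#' @param scheme a `gstn_scheme` or scheme name (default `"1-30"`).
#' @param balanced subsample the majority class to the minority size?
#' @param seed integer seed controlling the balancing draw.
#' @param n_max heavy-atom cap (molecules with `n_heavy >= n_max` dropped).
#' @return an object of class `gstn_dataset`: `records` (data frame `id`,
#'   `smiles`, `ic50_um`, `label`), `scheme`, `n_undefined_removed`,
#'   `n_size_filtered`, `n_unparseable`.
#' @export
build_dataset <- function(records, scheme = "1-30", balanced = FALSE,
                          seed = 1L, n_max = 45L) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_activity_table(records)
  }
  stopifnot(all(c("id", "smiles", "ic50_um") %in% names(records)))
  if (!inherits(scheme, "gstn_scheme")) scheme <- threshold_scheme(scheme)

  n_unparseable <- 0L
  n_size_filtered <- 0L
  if (nrow(records)) {
    mols <- parse_molecules(records$smiles)
    parseable <- !vapply(mols, is.null, logical(1))
    n_unparseable <- sum(!parseable)
    if (n_unparseable) {
      warning(n_unparseable, " unparseable SMILES removed (rows ",
              paste(utils::head(which(!parseable), 5L), collapse = ", "),
              if (n_unparseable > 5L) " ..." else "", ")")
    }
    records <- records[parseable, , drop = FALSE]
    mols <- mols[parseable]
    small <- vapply(mols, function(m) m$n_heavy < n_max, logical(1))
    n_size_filtered <- sum(!small)
    records <- records[small, , drop = FALSE]
  }

  label <- if (nrow(records)) assign_label(records$ic50_um, scheme) else character(0)
  n_undefined <- sum(label == "undefined")
  keep <- label != "undefined"
  records <- records[keep, , drop = FALSE]
  records$label <- label[keep]

  if (balanced && nrow(records)) {
    counts <- table(factor(records$label, c("blocker", "non_blocker")))
    minority <- min(counts)
    set.seed(seed)   # deterministic subsample of the majority class
    keep_idx <- unlist(lapply(names(counts), function(cl) {
      idx <- which(records$label == cl)
      if (length(idx) > minority) sort(sample(idx, minority)) else idx
    }))
    records <- records[sort(keep_idx), , drop = FALSE]
  }
  rownames(records) <- NULL
  if (!nrow(records)) {
    warning("empty dataset after filtering")
  }
  structure(
    list(records = records, scheme = scheme,
         n_undefined_removed = n_undefined,
         n_size_filtered = n_size_filtered,
         n_unparseable = n_unparseable),
    class = "gstn_dataset"
  )
}

#' Summarize a labeled dataset
#'
#' @param ds a `gstn_dataset`.
#' @return data frame with per-class counts, total, and removed counts.
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "gstn_dataset"))
  counts <- table(factor(ds$records$label, c("blocker", "non_blocker")))
  data.frame(
    scheme = ds$scheme$name,
    blocker = as.integer(counts[["blocker"]]),
    non_blocker = as.integer(counts[["non_blocker"]]),
    total = nrow(ds$records),
    undefined_removed = ds$n_undefined_removed,
    size_filtered = ds$n_size_filtered,
    stringsAsFactors = FALSE
  )
}

#' @export
print.gstn_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat("<labeled dataset> scheme ", s$scheme, ": ", s$blocker, " blockers, ",
      s$non_blocker, " non-blockers (", s$undefined_removed,
      " undefined removed, ", s$size_filtered, " size-filtered)\n", sep = "")
  invisible(x)
}

#' Dataset structural diversity
#'
#' One minus the mean pairwise Tanimoto similarity over circular
#' fingerprints; 0 for a set of identical molecules, approaching 1 for
#' structurally unrelated ones.
#'
#' @param ds a `gstn_dataset`, or a character vector of SMILES.
#' @param fp_bits fingerprint length.
#' @param fp_diameter circular diameter.
#' @return a number in `[0, 1]`.
#' @export
dataset_diversity <- function(ds, fp_bits = 1024L, fp_diameter = 4L) {
  smiles <- if (inherits(ds, "gstn_dataset")) ds$records$smiles else ds
  if (length(smiles) < 2L) {
    stop("diversity needs at least two molecules", call. = FALSE)
  }
  fp <- ecfp(smiles, n_bits = fp_bits, diameter = fp_diameter)
  counts <- rowSums(fp)
  inter <- tcrossprod(fp)           # pairwise intersection sizes
  un <- outer(counts, counts, "+") - inter
  sim <- ifelse(un == 0, 1, inter / un)
  m <- length(smiles)
  1 - mean(sim[upper.tri(sim)])
}
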