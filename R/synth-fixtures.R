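# Embedded reference tables and the synthetic molecule/activity generator.

#' Load an embedded fixture table
#'
#' Two reference tables ship with the package as tab-delimited text:
#' `"fda50"` (50 FDA-approved drugs with hERG IC50 values, the reference
#' labels under five thresholding schemes, the corresponding model
#' predictions, and an `external` flag for compounds outside the training
#' corpus) and `"scaffold_cases"` (activity-cliff case studies: SMILES,
#' printed Murcko scaffold, class, per-model verdicts and train/test
#' split). SMILES and scaffold strings are stored verbatim, including the
#' typographic spaces of the printed tables; sanitized copies are added as
#' `smiles` / `murcko` columns on load.
#'
#' @param name `"fda50"` or `"scaffold_cases"`.
#' @return data frame.
#' @export
load_fixture <- function(name = c("fda50", "scaffold_cases")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "gstn")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (name == "scaffold_cases") {
    df$smiles <- sanitize_smiles(df$smiles_verbatim)
    df$murcko <- sanitize_smiles(df$murcko_verbatim)
  }
  df
}

# scheme names of the five label/prediction column pairs in fda50
fda50_schemes <- function() {
  c(label_1 = "1", label_1_10 = "1-10", label_1_20 = "1-20",
    label_1_30 = "1-30", label_1_40 = "1-40")
}

# map printed table cells to internal labels
normalize_printed_label <- function(x) {
  out <- rep(NA_character_, length(x))
  out[x == "Blocker"] <- "blocker"
  out[x == "Non-blocker"] <- "non_blocker"
  out[x == "-"] <- "undefined"
  out
}

# ---- synthetic generator ---------------------------------------------------

# fragment grammar: carbocyclic scaffold templates with one or two
# valence-safe attachment sites, plus substituent pools. Heteroatoms enter
# only through the {R1} substituent, so the heteroatom rule is cleanly
# identified with a single substitution.
synth_templates <- function() {
  list(
    list(smiles = "c1ccc({R1})cc1", aromatic = TRUE),
    list(smiles = "c1cc({R2})ccc1{R1}", aromatic = TRUE),
    list(smiles = "c1ccc2cc({R1})ccc2c1", aromatic = TRUE),
    list(smiles = "c1cc({R2})c2cc({R1})ccc2c1", aromatic = TRUE),
    list(smiles = "C1Cc2ccc({R1})cc2C1", aromatic = TRUE),
    list(smiles = "C1CCC({R1})CC1", aromatic = FALSE),
    list(smiles = "C1CC({R2})CCC1{R1}", aromatic = FALSE),
    list(smiles = "C1CCCC({R1})C1{R2}", aromatic = FALSE)
  )
}

synth_hetero_subs <- function() {
  c("N", "O", "NC", "OC", "N(C)C", "S", "SC", "C(=O)N", "C#N", "CCO", "CN")
}

synth_carbo_subs <- function() {
  c("C", "CC", "CCC", "C(C)C", "C(C)(C)C", "C=C", "F", "Cl", "Br",
    "C(F)(F)F", "CCl")
}

#' Specification for the synthetic benchmark
#'
#' Describes the fragment grammar and the planted activity rule of the
#' synthetic corpus: molecules are carbocyclic scaffolds decorated with
#' substituents; the mean log10 IC50 of a molecule is set by a predicate
#' computable from its predefined subgraphs (default: presence of any
#' N/O/S heteroatom makes the molecule potent), with Gaussian noise on the
#' log scale. A fraction of molecules is generated as activity-cliff
#' pairs: same scaffold and decoration, differing only in the
#' rule-triggering substituent, hence sharing a Murcko scaffold while
#' receiving divergent potencies.
#'
#' @param n number of molecules.
#' @param rule `"heteroatom"` (potency driven by N/O/S presence) or
#'   `"aromatic"` (driven by aromatic-ring presence).
#' @param noise_sd standard deviation of log10(IC50) around the rule mean.
#' @param cliff_fraction fraction of molecules generated as matched cliff
#'   pairs.
#' @param mu_active,mu_inactive mean log10(IC50 / uM) of rule-triggered
#'   (potent, 0.1 uM) and untriggered (100 uM) molecules.
#' @param seed integer seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n = 1000L, rule = c("heteroatom", "aromatic"),
                       noise_sd = 0.5, cliff_fraction = 0.2,
                       mu_active = -1, mu_inactive = 2, seed = 1L) {
  rule <- match.arg(rule)
  structure(
    list(n = as.integer(n), rule = rule, noise_sd = noise_sd,
         cliff_fraction = cliff_fraction, mu_active = mu_active,
         mu_inactive = mu_inactive, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

fill_template <- function(template, r1, r2) {
  s <- sub("{R1}", r1, template, fixed = TRUE)
  sub("{R2}", r2, s, fixed = TRUE)
}

#' Generate synthetic molecules
#'
#' Deterministic under the spec's seed. The first
#' `2 * floor(n * cliff_fraction / 2)` entries form consecutive
#' activity-cliff pairs (identical scaffold and decoration, one
#' rule-triggering and one neutral substituent).
#'
#' @param spec a [synth_spec()].
#' @return character vector of `spec$n` SMILES strings.
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  templates <- synth_templates()
  hetero <- synth_hetero_subs()
  carbo <- synth_carbo_subs()
  n <- spec$n
  n_pairs <- floor(n * spec$cliff_fraction / 2)
  out <- character(n)

  aromatic_rule <- spec$rule == "aromatic"
  pick_template <- function(trigger) {
    if (!aromatic_rule) return(templates[[sample.int(length(templates), 1L)]])
    pool <- Filter(function(t) t$aromatic == trigger, templates)
    pool[[sample.int(length(pool), 1L)]]
  }
  pick_r1 <- function(trigger) {
    if (aromatic_rule) return(sample(carbo, 1L))
    if (trigger) sample(hetero, 1L) else sample(carbo, 1L)
  }

  i <- 1L
  for (p in seq_len(n_pairs)) {
    if (aromatic_rule) {
      # cliff pairs need a shared scaffold, which an aromatic-presence rule
      # cannot provide; fall back to substituent-differing pairs
      tmpl <- pick_template(TRUE)
    } else {
      tmpl <- templates[[sample.int(length(templates), 1L)]]
    }
    r2 <- sample(carbo, 1L)
    out[i] <- fill_template(tmpl$smiles, sample(hetero, 1L), r2)
    out[i + 1L] <- fill_template(tmpl$smiles, sample(carbo, 1L), r2)
    i <- i + 2L
  }
  while (i <= n) {
    trigger <- stats::runif(1) < 0.5
    tmpl <- pick_template(trigger)
    out[i] <- fill_template(tmpl$smiles, pick_r1(trigger), sample(carbo, 1L))
    i <- i + 1L
  }
  out
}

# the planted predicate, computed from the molecule's subgraph structure
rule_trigger <- function(mols, rule) {
  vapply(mols, function(mol) {
    if (rule == "heteroatom") length(heteroatom_set(mol)) > 0
    else length(aromatic_ring_atoms(mol)) > 0
  }, logical(1))
}

#' Plant IC50 activities on molecules
#'
#' Draws `log10(IC50) ~ Normal(mu_rule(mol), noise_sd)` where the mean is
#' decided by the spec's rule predicate evaluated on each molecule's
#' subgraph structure (not on hidden generator state). With
#' `noise_sd = 0` the IC50 is exactly rule-determined.
#'
#' @param smiles character vector of SMILES.
#' @param spec a [synth_spec()].
#' @return data frame with `id`, `smiles`, `ic50_um`.
#' @export
plant_activity <- function(smiles, spec) {
  stopifnot(inherits(spec, "synth_spec"))
  mols <- parse_molecules(smiles, on_error = "stop")
  trigger <- rule_trigger(mols, spec$rule)
  mu <- ifelse(trigger, spec$mu_active, spec$mu_inactive)
  set.seed(spec$seed + 1L)
  log_ic50 <- stats::rnorm(length(smiles), mean = mu, sd = spec$noise_sd)
  data.frame(
    id = sprintf("SYN%05d", seq_along(smiles)),
    smiles = smiles,
    ic50_um = 10^log_ic50,
    stringsAsFactors = FALSE
  )
}

#' Build the full synthetic benchmark
#'
#' Generates molecules, plants activities, and returns the ground-truth
#' rule labels and the cliff-pair index.
#'
#' @param spec a [synth_spec()].
#' @return list with `records` (activity table), `truth` (oracle labels
#'   `"blocker"` / `"non_blocker"` from the planted rule), `cliff_pairs`
#'   (two-column index matrix), and `spec`.
#' @export
make_benchmark <- function(spec = synth_spec()) {
  smiles <- generate_molecules(spec)
  records <- plant_activity(smiles, spec)
  mols <- parse_molecules(smiles, on_error = "stop")
  trigger <- rule_trigger(mols, spec$rule)
  n_pairs <- floor(spec$n * spec$cliff_fraction / 2)
  cliff_pairs <- if (n_pairs > 0) {
    cbind(first = seq(1L, by = 2L, length.out = n_pairs),
          second = seq(2L, by = 2L, length.out = n_pairs))
  } else {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("first", "second")))
  }
  list(records = records,
       truth = ifelse(trigger, "blocker", "non_blocker"),
       cliff_pairs = cliff_pairs,
       spec = spec)
}
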