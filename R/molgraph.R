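#' @keywords internal
#' @useDynLib probekit, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Feature layout (kept constant across a dataset):
#   atoms : element one-hot (11 named + other), mass/100, valence one-hot 0..6,
#           formal charge one-hot -2..+2, chirality tag one-hot
#           (none/cw/ccw/other), hybridization one-hot (sp/sp2/sp3/other),
#           aromatic flag                                        -> 34 columns
#   bonds : order one-hot (single/double/triple/aromatic), conjugation flag,
#           ring flag, stereo one-hot (none/Z/E/other)           -> 10 columns
PK_D_ATOM <- 34L
PK_D_BOND <- 10L

pk_one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

pk_atom_feature_row <- function(element, mass, charge, aromatic, valence,
                                hybrid, chirality = "none") {
  el <- match(element, PK_ELEMENTS)
  el_oh <- pk_one_hot(if (is.na(el)) length(PK_ELEMENTS) + 1L else el,
                      length(PK_ELEMENTS) + 1L)
  val_oh <- pk_one_hot(min(max(valence, 0L), 6L) + 1L, 7L)
  chg_oh <- pk_one_hot(min(max(charge, -2L), 2L) + 3L, 5L)
  chi_oh <- pk_one_hot(match(chirality, c("none", "cw", "ccw", "other")), 4L)
  hyb_oh <- pk_one_hot(match(hybrid, c("sp", "sp2", "sp3", "other")), 4L)
  c(el_oh, mass / 100, val_oh, chg_oh, chi_oh, hyb_oh, as.numeric(aromatic))
}

pk_bond_feature_row <- function(order, aromatic, conjugated, in_ring,
                                stereo = "none") {
  kind <- if (aromatic) 4L else min(max(order, 1L), 3L)
  c(pk_one_hot(kind, 4L), as.numeric(conjugated), as.numeric(in_ring),
    pk_one_hot(match(stereo, c("none", "z", "e", "other")), 4L))
}

# Build a mol_graph from parsed atom/bond tables. Separated from the SMILES
# front end so tests can featurize explicitly permuted atom orderings.
pk_build_graph <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  n <- nrow(atoms)
  nb <- nrow(bonds)

  # Explicit (heavy-atom) valence: aromatic bonds count 1.5.
  contrib <- if (nb) ifelse(bonds$aromatic, 1.5, bonds$order) else numeric(0)
  valence <- numeric(n)
  n_double <- integer(n)
  n_triple <- integer(n)
  if (nb) {
    for (k in seq_len(nb)) {
      valence[bonds$a1[k]] <- valence[bonds$a1[k]] + contrib[k]
      valence[bonds$a2[k]] <- valence[bonds$a2[k]] + contrib[k]
      if (!bonds$aromatic[k] && bonds$order[k] == 2L) {
        n_double[bonds$a1[k]] <- n_double[bonds$a1[k]] + 1L
        n_double[bonds$a2[k]] <- n_double[bonds$a2[k]] + 1L
      }
      if (!bonds$aromatic[k] && bonds$order[k] == 3L) {
        n_triple[bonds$a1[k]] <- n_triple[bonds$a1[k]] + 1L
        n_triple[bonds$a2[k]] <- n_triple[bonds$a2[k]] + 1L
      }
    }
  }
  hybrid <- ifelse(
    n_triple > 0 | n_double >= 2, "sp",
    ifelse(atoms$aromatic | n_double == 1, "sp2", "sp3")
  )
  unsat <- hybrid %in% c("sp", "sp2")

  atom_features <- matrix(0, n, PK_D_ATOM)
  for (i in seq_len(n)) {
    atom_features[i, ] <- pk_atom_feature_row(
      atoms$element[i], atoms$mass[i], atoms$charge[i], atoms$aromatic[i],
      round(valence[i]), hybrid[i]
    )
  }

  if (nb == 0) {
    return(structure(
      list(
        n_atoms = n, n_edges = 0L,
        atom_features = atom_features,
        bond_features = matrix(0, 0, PK_D_BOND),
        edges = matrix(integer(0), 0, 2,
                       dimnames = list(NULL, c("src", "tgt"))),
        rev_index = integer(0),
        smiles = mol$smiles
      ),
      class = "mol_graph"
    ))
  }

  conj <- bonds$aromatic | (unsat[bonds$a1] & unsat[bonds$a2])
  bf_und <- matrix(0, nb, PK_D_BOND)
  for (k in seq_len(nb)) {
    bf_und[k, ] <- pk_bond_feature_row(
      bonds$order[k], bonds$aromatic[k], conj[k], bonds$in_ring[k]
    )
  }

  # Directed edges: bond k expands to edges 2k-1 (a1 -> a2) and 2k (a2 -> a1);
  # the reverse index is the involution swapping the pair.
  src <- as.vector(rbind(bonds$a1, bonds$a2))
  tgt <- as.vector(rbind(bonds$a2, bonds$a1))
  rev_index <- as.vector(rbind(seq_len(nb) * 2L, seq_len(nb) * 2L - 1L))
  bond_features <- bf_und[rep(seq_len(nb), each = 2), , drop = FALSE]

  structure(
    list(
      n_atoms = n, n_edges = 2L * nb,
      atom_features = atom_features,
      bond_features = bond_features,
      edges = cbind(src = src, tgt = tgt),
      rev_index = rev_index,
      smiles = mol$smiles
    ),
    class = "mol_graph"
  )
}

#' Featurize a molecule as a directed molecular graph
#'
#' Converts a SMILES string into the featurized directed graph consumed by
#' the message-passing encoder: per-atom features (element, scaled mass,
#' valence, formal charge, chirality tag, hybridization, aromaticity) and
#' per-directed-edge bond features (bond order, conjugation, ring
#' membership, stereochemistry tag). Hydrogens are implicit; every
#' undirected bond contributes two directed edges linked by `rev_index`.
#'
#' @param smiles A single SMILES string.
#' @return A `mol_graph` object: a list with `n_atoms`, `n_edges`,
#'   `atom_features` (n_atoms x 34), `bond_features` (n_edges x 10),
#'   `edges` (n_edges x 2, columns `src`, `tgt`), and `rev_index`.
#' @examples
#' g <- featurize_molecule("CC")
#' g$n_atoms  # 2
#' g$n_edges  # 2 directed edges for the single bond
#' @export
featurize_molecule <- function(smiles) {
  pk_build_graph(pk_parse_mol(smiles))
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, ": ", x$n_atoms, " atoms, ",
      x$n_edges, " directed edges\n", sep = "")
  invisible(x)
}

#' Encode a prediction-condition context
#'
#' The activity classifier is conditioned on a wavelength pair; the property
#' regressors are conditioned on a solvent structure. A wavelength pair is
#' min-max scaled by its admissible range (absorption 300-900 nm, emission
#' 400-1200 nm) to `[0, 1]^2`; a solvent SMILES is returned as a featurized
#' `mol_graph` to be embedded by the solvent-specific encoder.
#'
#' @param abs_nm,em_nm Absorption and emission query wavelengths in nm.
#' @param solvent_smiles A solvent SMILES string (alternative to wavelengths).
#' @return A numeric length-2 vector in `[0,1]^2`, or a `mol_graph` when
#'   `solvent_smiles` is given.
#' @examples
#' encode_condition(600, 800)  # c(0.5, 0.5)
#' @export
encode_condition <- function(abs_nm = NULL, em_nm = NULL, solvent_smiles = NULL) {
  if (!is.null(solvent_smiles)) {
    return(featurize_molecule(solvent_smiles))
  }
  stopifnot(is.numeric(abs_nm), is.numeric(em_nm))
  if (abs_nm < 300 || abs_nm > 900) {
    abort("absorption query outside [300, 900] nm", class = "probekit_domain_error")
  }
  if (em_nm < 400 || em_nm > 1200) {
    abort("emission query outside [400, 1200] nm", class = "probekit_domain_error")
  }
  c((abs_nm - 300) / 600, (em_nm - 400) / 800)
}
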