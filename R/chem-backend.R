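#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
NULL

# Element vocabulary used across featurization; anything else maps to "other".
PK_ELEMENTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")

PK_MASSES <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

pk_invalid_structure <- function(smiles) {
  abort(
    paste0("invalid molecular structure: ", encodeString(smiles)),
    class = "probekit_invalid_structure",
    smiles = smiles
  )
}

#' Canonicalize SMILES strings
#'
#' Maps every spelling of the same structure to one canonical SMILES string
#' (OpenBabel canonical form), so that records can be merged and cached by
#' structure identity. Canonicalization is idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If `TRUE` (default), an unparsable string raises an
#'   invalid-structure error naming the offending input. If `FALSE`,
#'   unparsable entries yield `NA` (used by the curation pipeline, which
#'   counts and drops them).
#' @return Character vector of canonical SMILES, same length as `smiles`.
#' @examples
#' canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1")) # identical outputs
#' @export
canonicalize_smiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  bad_input <- is.na(smiles) | !nzchar(smiles)
  out <- rep(NA_character_, length(smiles))
  idx <- which(!bad_input)
  if (length(idx)) {
    # Tag each line with its index so invalid entries (which OpenBabel
    # silently drops) cannot shift the alignment of the output.
    payload <- paste0(smiles[idx], " pk", seq_along(idx), collapse = "\n")
    res <- suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(payload, "\n"))
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(parts) >= 2 && grepl("^pk[0-9]+$", parts[[2]])) {
        k <- as.integer(sub("^pk", "", parts[[2]]))
        out[idx[k]] <- parts[[1]]
      }
    }
    # OpenBabel stops the batch at the first unparsable line; resolve the
    # remainder one at a time so later valid entries are not lost.
    for (k in idx[is.na(out[idx])]) {
      res1 <- suppressWarnings(
        ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles[k], "\n"))
      )
      tok <- strsplit(res1, "[ \t\n]+")[[1]]
      if (length(tok) >= 1 && nzchar(tok[[1]])) out[k] <- tok[[1]]
    }
  }
  if (strict && anyNA(out)) {
    pk_invalid_structure(smiles[which(is.na(out))[1]])
  }
  out
}

#' Is a SMILES string parsable?
#'
#' @param smiles Character vector.
#' @return Logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonicalize_smiles(smiles, strict = FALSE))
}

# Decode the V2000 atom-block charge column (old-style codes).
pk_decode_charge <- function(code) {
  chg <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)
  out <- rep(0L, length(code))
  hit <- as.character(code) %in% names(chg)
  out[hit] <- chg[as.character(code[hit])]
  out
}

# Parse one SMILES into plain atom/bond tables (heavy atoms only, implicit
# hydrogens). This is the single entry point to the OpenBabel backend for
# graph work; everything downstream consumes these tables.
#
# Returns list(atoms = tibble(element, charge, aromatic, mass),
#              bonds = tibble(a1, a2, order, aromatic, in_ring))
pk_parse_mol <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (is.na(smiles) || !nzchar(smiles)) pk_invalid_structure(smiles)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0) pk_invalid_structure(smiles)
  sdf1 <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf1)
  if (is.null(dim(ab)) || nrow(ab) == 0) pk_invalid_structure(smiles)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  n <- length(elements)
  charge <- if ("C6" %in% colnames(ab)) pk_decode_charge(ab[, "C6"]) else rep(0L, n)

  bb <- ChemmineR::bondblock(sdf1)
  bonds <- tibble(a1 = integer(0), a2 = integer(0), order = integer(0))
  if (!is.null(dim(bb)) && nrow(bb) > 0 && ncol(bb) >= 3) {
    b <- as_tibble(as.data.frame(bb[, 1:3, drop = FALSE]))
    names(b) <- c("a1", "a2", "order")
    b <- dplyr::filter(b, .data$a1 >= 1, .data$a2 >= 1)
    bonds <- dplyr::mutate(b, dplyr::across(dplyr::everything(), as.integer))
  }

  # Ring perception + aromaticity from the backend.
  atom_arom <- rep(FALSE, n)
  atom_ring <- rep(FALSE, n)
  bond_ring <- rep(FALSE, nrow(bonds))
  bond_arom <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf1, type = "all", arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    ring_sets <- lapply(rg$RINGS, function(r) as.integer(sub("^.*_", "", r)))
    arom_flags <- rg$AROMATIC
    bond_key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
    for (k in seq_along(ring_sets)) {
      members <- ring_sets[[k]]
      atom_ring[members] <- TRUE
      m <- length(members)
      pairs <- cbind(members, members[c(2:m, 1)])
      keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
      bond_ring[bond_key %in% keys] <- TRUE
      if (isTRUE(arom_flags[[k]])) {
        atom_arom[members] <- TRUE
        bond_arom[bond_key %in% keys] <- TRUE
      }
    }
  }

  atoms <- tibble(
    element = elements,
    charge = charge,
    aromatic = atom_arom,
    in_ring = atom_ring,
    mass = unname(ifelse(elements %in% names(PK_MASSES), PK_MASSES[elements], 100))
  )
  bonds$aromatic <- bond_arom
  bonds$in_ring <- bond_ring
  list(atoms = atoms, bonds = bonds, smiles = smiles)
}

# Serialize atom/bond tables back to a V2000 molfile (no coordinates).
# Aromatic bonds are written with order 4; OpenBabel re-perceives them.
pk_mol_to_sdf <- function(atoms, bonds) {
  n <- nrow(atoms)
  header <- c("", "  probekit", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)))
  atom_lines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    atoms$element
  )
  bond_lines <- character(0)
  if (nrow(bonds) > 0) {
    ord <- ifelse(bonds$aromatic, 4L, bonds$order)
    bond_lines <- sprintf("%3d%3d%3d  0", bonds$a1, bonds$a2, ord)
  }
  chg_lines <- character(0)
  charged <- which(atoms$charge != 0)
  if (length(charged)) {
    chg_lines <- vapply(charged, function(i) {
      sprintf("M  CHG  1%4d%4d", i, atoms$charge[i])
    }, character(1))
  }
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
        collapse = "\n")
}

# Canonical SMILES of an atom/bond-table molecule (used by scaffold pruning).
pk_mol_to_smiles <- function(atoms, bonds) {
  if (nrow(atoms) == 0) return("")
  sdf <- pk_mol_to_sdf(atoms, bonds)
  res <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", sdf))
  out <- strsplit(res, "[ \t\n]+")[[1]]
  if (length(out) == 0 || !nzchar(out[[1]])) pk_invalid_structure("<fragment>")
  out[[1]]
}
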