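# Independent loop-based implementations used as oracles. These mirror the
# stated update equations edge by edge and are deliberately naive.

oracle_encode <- function(g, enc, depth, aggregation = "mean") {
  relu <- function(x) pmax(x, 0)
  E <- g$n_edges
  h <- ncol(enc$W_in)
  H <- matrix(0, max(E, 0), h)
  for (e in seq_len(E)) {
    H[e, ] <- relu(c(g$atom_features[g$edges[e, "src"], ],
                     g$bond_features[e, ]) %*% enc$W_in)
  }
  for (t in seq_len(depth)) {
    Hn <- matrix(0, max(E, 0), h)
    for (e in seq_len(E)) {
      m <- numeric(h)
      for (ep in seq_len(E)) {
        if (g$edges[ep, "tgt"] == g$edges[e, "src"] && ep != g$rev_index[e]) {
          m <- m + H[ep, ]
        }
      }
      Hn[e, ] <- relu(c(H[e, ], m) %*% enc$W_h)
    }
    H <- Hn
  }
  A <- matrix(0, g$n_atoms, h)
  for (v in seq_len(g$n_atoms)) {
    s <- numeric(h)
    for (e in seq_len(E)) if (g$edges[e, "tgt"] == v) s <- s + H[e, ]
    A[v, ] <- relu(c(g$atom_features[v, ], s) %*% enc$W_a)
  }
  if (aggregation == "mean") colMeans(A) else colSums(A)
}

oracle_ffn <- function(u, ffn) {
  x <- u
  L <- length(ffn)
  for (l in seq_len(L)) {
    z <- as.numeric(x %*% ffn[[l]]$W + ffn[[l]]$b)
    x <- if (l < L) pmax(z, 0) else z
  }
  x
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Small molecules (<= 5 heavy atoms) spanning the structural cases the
# encoder must handle: no bonds, chains, branching, rings, aromatics,
# multiple bond orders, heteroatoms.
tiny_fixture_smiles <- function() {
  c("C", "CC", "CCC", "CC(C)C", "C1CC1", "C=CC", "C#CC", "CCO",
    "CC=O", "CC#N", "C1CCC1", "CS", "ClCCl")
}

# Rewrite a molecule's SMILES with a permuted atom order by permuting its
# parsed atom/bond tables and rebuilding the graph directly.
permuted_graph <- function(smiles, seed) {
  mol <- probekit:::pk_parse_mol(smiles)
  n <- nrow(mol$atoms)
  perm_mol <- probekit:::pk_with_seed(seed, {
    perm <- sample.int(n)
    inv <- order(perm)
    atoms <- mol$atoms[perm, , drop = FALSE]
    bonds <- mol$bonds
    if (nrow(bonds)) {
      bonds$a1 <- inv[bonds$a1]
      bonds$a2 <- inv[bonds$a2]
      bonds <- bonds[sample.int(nrow(bonds)), , drop = FALSE]
    }
    list(atoms = atoms, bonds = bonds)
  })
  probekit:::pk_build_graph(list(atoms = perm_mol$atoms,
                                 bonds = perm_mol$bonds,
                                 smiles = mol$smiles))
}

small_seeded_cls <- function(hidden = 16L, seed = 11L, ...) {
  cfg <- encoder_config("classification", hidden = hidden,
                        ffn_hidden = hidden, seed = seed, ...)
  list(cfg = cfg, params = probekit:::pk_init_params(cfg))
}

small_seeded_reg <- function(hidden = 16L, seed = 12L, ...) {
  cfg <- encoder_config("regression", target_property = "em_wavelength",
                        hidden = hidden, solvent_hidden = hidden,
                        ffn_hidden = hidden, seed = seed, ...)
  list(cfg = cfg, params = probekit:::pk_init_params(cfg))
}
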