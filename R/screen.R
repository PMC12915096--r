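#' Bemis-Murcko scaffold of a molecule
#'
#' The molecule's ring systems plus the linkers connecting them; side
#' chains are pruned by iterative removal of terminal atoms. Acyclic
#' molecules have no scaffold and yield the empty string.
#'
#' @param smiles A SMILES string (or vector).
#' @return Canonical scaffold SMILES, `""` for acyclic molecules.
#' @examples
#' murcko_scaffold("Cc1ccccc1")  # benzene
#' murcko_scaffold("CCO")        # ""
#' @export
murcko_scaffold <- function(smiles) {
  if (length(smiles) > 1) {
    return(vapply(smiles, murcko_scaffold, character(1), USE.NAMES = FALSE))
  }
  mol <- pk_parse_mol(smiles)
  atoms <- mol$atoms
  bonds <- mol$bonds
  if (nrow(bonds) == 0 || !any(bonds$in_ring)) return("")
  keep <- rep(TRUE, nrow(atoms))
  repeat {
    deg <- tabulate(c(bonds$a1[keep[bonds$a1] & keep[bonds$a2]],
                      bonds$a2[keep[bonds$a1] & keep[bonds$a2]]),
                    nbins = nrow(atoms))
    terminal <- keep & deg <= 1
    if (!any(terminal)) break
    keep[terminal] <- FALSE
  }
  idx <- which(keep)
  if (length(idx) == 0) return("")
  remap <- match(seq_len(nrow(atoms)), idx)
  sub_bonds <- bonds[keep[bonds$a1] & keep[bonds$a2], , drop = FALSE]
  sub_bonds$a1 <- remap[sub_bonds$a1]
  sub_bonds$a2 <- remap[sub_bonds$a2]
  pk_mol_to_smiles(atoms[idx, , drop = FALSE], sub_bonds)
}

#' Extended-connectivity fingerprints
#'
#' Circular (ECFP-style) fingerprints of the given radius hashed to a
#' fixed-length bit vector. The backend emits 4096-bit fingerprints, which
#' are folded by bitwise OR to the requested width (2048 by default, i.e.
#' ECFP4 at radius 2).
#'
#' @param smiles Character vector of SMILES.
#' @param radius Circular radius (2 for ECFP4).
#' @param n_bits Output width; must divide the backend's 4096.
#' @return Integer 0/1 matrix, one row per molecule.
#' @export
ecfp_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  stopifnot(radius %in% c(1, 2, 3))
  if (4096 %% n_bits != 0) {
    abort("n_bits must divide 4096", class = "probekit_config_error")
  }
  canon <- canonicalize_smiles(smiles)  # errors on invalid input
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(canon, paste0("m", seq_along(canon))))
  )
  fp_name <- paste0("ECFP", 2 * radius)
  fp <- ChemmineR::fingerprintOB(sdf, fp_name)
  m <- methods::slot(fp, "fpma")
  while (ncol(m) > n_bits) {
    half <- ncol(m) / 2
    m <- (m[, 1:half, drop = FALSE] | m[, half + 1:half, drop = FALSE]) * 1L
  }
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Tanimoto similarity between two bit vectors
#' @param a,b Integer 0/1 vectors.
#' @return Jaccard/Tanimoto coefficient.
#' @export
tanimoto <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

#' Project fingerprints into 2D chemical space with t-SNE
#'
#' Exact t-SNE (perplexity 30, seed 42 by default) on the fingerprint
#' matrix. Perplexity is auto-reduced with a warning when there are fewer
#' than `3 * perplexity + 1` molecules.
#'
#' @param fingerprints Matrix from [ecfp_fingerprint()].
#' @param perplexity t-SNE perplexity.
#' @param seed Seed for the embedding initialization.
#' @param max_iter Gradient iterations.
#' @return Tibble with `tsne1`, `tsne2` (one row per molecule).
#' @export
chemspace_embed <- function(fingerprints, perplexity = 30, seed = 42,
                            max_iter = 500) {
  Y <- pk_tsne(as.matrix(fingerprints), perplexity = perplexity, seed = seed,
               max_iter = max_iter)
  tibble(tsne1 = Y[, 1], tsne2 = Y[, 2])
}

#' Ranked scaffold frequency table
#'
#' Counts Bemis-Murcko scaffolds across a library; ties are broken
#' lexicographically and acyclic molecules are pooled in a dedicated
#' `"<acyclic>"` bin.
#'
#' @param smiles Character vector of SMILES (non-empty).
#' @param k Number of top scaffolds to return (all if fewer).
#' @return Tibble with `scaffold`, `n`, sorted by decreasing count.
#' @export
scaffold_frequencies <- function(smiles, k = 20) {
  if (length(smiles) == 0) abort("empty library", class = "probekit_data_error")
  sc <- murcko_scaffold(smiles)
  sc[sc == ""] <- "<acyclic>"
  tab <- tibble(scaffold = sc) |>
    dplyr::count(.data$scaffold) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$scaffold)
  utils::head(tab, k)
}

#' Chemical-space characterization of a molecule set
#'
#' Computes ECFP4 fingerprints, Bemis-Murcko scaffolds, a 2D t-SNE
#' embedding, and the top-k scaffold frequency table in one pass.
#'
#' @param data Tibble with a `smiles` column (extra columns are carried
#'   through to the coordinates table).
#' @param perplexity,seed,max_iter Passed to [chemspace_embed()].
#' @param radius,n_bits Passed to [ecfp_fingerprint()].
#' @param top_k Scaffold table size.
#' @return A `chemspace_result`: list with `coords` (input columns +
#'   `scaffold`, `tsne1`, `tsne2`), `fingerprints`, and `scaffold_freq`.
#' @export
chemspace_analysis <- function(data, perplexity = 30, seed = 42,
                               max_iter = 500, radius = 2, n_bits = 2048,
                               top_k = 20) {
  stopifnot("smiles" %in% names(data))
  fp <- ecfp_fingerprint(data$smiles, radius, n_bits)
  coords <- chemspace_embed(fp, perplexity, seed, max_iter)
  out <- dplyr::bind_cols(
    tibble::as_tibble(data),
    tibble(scaffold = murcko_scaffold(data$smiles)),
    coords
  )
  structure(
    list(coords = out, fingerprints = fp,
         scaffold_freq = scaffold_frequencies(data$smiles, top_k)),
    class = "chemspace_result"
  )
}

#' @export
print.chemspace_result <- function(x, ...) {
  cat("<chemspace_result>", nrow(x$coords), "molecules,",
      nrow(x$scaffold_freq), "top scaffolds\n")
  invisible(x)
}

#' Two-step screening of a molecule library
#'
#' Step 1 scores every molecule for fluorescence activity under the given
#' wavelength pair: scores of molecules present in the classifier's
#' training cache (same structure and condition) are retrieved directly
#' without a model call; the classifier predicts the rest. Molecules
#' scoring below `threshold` are excluded. Step 2 attaches the seven
#' photophysical properties (retrieved from the regression caches where
#' measured, predicted otherwise) to the survivors only.
#'
#' @param library Tibble with `smiles` (optional `target` annotation).
#' @param l1_model Trained classification `dmpnn_model`.
#' @param l2_models Named list of regression `dmpnn_model`s keyed by
#'   property (any subset of [pk_properties()]).
#' @param wavelength_pair `c(abs_nm, em_nm)` screening condition.
#' @param solvent_smiles Solvent condition for the property predictions.
#' @param threshold Activity-score cut in \[0, 1\]; survivors have
#'   `score >= threshold`.
#' @return Tibble sorted by score (descending, ties by SMILES): `smiles`,
#'   optional `target`, `provenance` (`"retrieved"`/`"predicted"`),
#'   `activity_score`, `passed_l1`, and one column per property (NA unless
#'   `passed_l1`). Invalid SMILES rows are dropped; their count is in
#'   `attr(, "n_invalid")`.
#' @export
two_step_screen <- function(library, l1_model, l2_models = list(),
                            wavelength_pair, solvent_smiles = "CC#N",
                            threshold = 0.5) {
  stopifnot(inherits(l1_model, "dmpnn_model"),
            l1_model$cfg$task == "classification")
  if (threshold < 0 || threshold > 1) {
    abort("threshold must lie in [0, 1]", class = "probekit_domain_error")
  }
  df <- tibble::as_tibble(library)
  canon <- canonicalize_smiles(df$smiles, strict = FALSE)
  n_invalid <- sum(is.na(canon))
  df$smiles <- canon
  df <- df[!is.na(canon), , drop = FALSE]
  solvent_canon <- canonicalize_smiles(solvent_smiles)

  key <- paste(df$smiles, wavelength_pair[1], wavelength_pair[2], sep = "|")
  hit <- match(key, l1_model$cache$key)
  df$provenance <- ifelse(is.na(hit), "predicted", "retrieved")
  df$activity_score <- NA_real_
  df$activity_score[!is.na(hit)] <- l1_model$cache$stored[hit[!is.na(hit)]]

  miss <- which(is.na(hit))
  if (length(miss)) {
    pred_in <- tibble(
      smiles = df$smiles[miss],
      abs_query = wavelength_pair[1], em_query = wavelength_pair[2]
    )
    df$activity_score[miss] <- predict(l1_model, pred_in)$.pred
  }
  df$passed_l1 <- df$activity_score >= threshold

  for (prop in pk_properties()) df[[prop]] <- NA_real_
  surv <- which(df$passed_l1)
  for (prop in names(l2_models)) {
    model <- l2_models[[prop]]
    stopifnot(inherits(model, "dmpnn_model"), model$cfg$task == "regression")
    if (!length(surv)) next
    pkey <- paste(df$smiles[surv], solvent_canon, sep = "|")
    phit <- match(pkey, model$cache$key)
    vals <- rep(NA_real_, length(surv))
    vals[!is.na(phit)] <- model$cache$stored[phit[!is.na(phit)]]
    pmiss <- which(is.na(phit))
    if (length(pmiss)) {
      pin <- tibble(smiles = df$smiles[surv][pmiss],
                    solvent_smiles = solvent_canon)
      vals[pmiss] <- predict(model, pin)$.pred
    }
    df[[prop]][surv] <- vals
  }

  out <- dplyr::arrange(df, dplyr::desc(.data$activity_score), .data$smiles)
  attr(out, "n_invalid") <- n_invalid
  out
}
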