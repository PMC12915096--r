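# Run code under a temporary RNG state, restoring the caller's stream.
pk_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Donor / acceptor fragments and the two backbone families, enumerated
# literally. Donor and acceptor strengths are the planted D and A values.
PK_DONORS <- tibble::tribble(
  ~donor_smiles, ~donor_strength,
  "C",           0,
  "CO",          0.5,
  "CN(C)",       1
)

PK_ACCEPTORS <- tibble::tribble(
  ~acceptor_smiles, ~acceptor_strength,
  "C",              0,
  "C=O",            0.5,
  "C#N",            1
)

# family "chain":     <donor><bridge><acceptor>
# family "phenylene": <donor>c1ccc(<bridge><acceptor>)cc1
PK_FAMILIES <- c("chain", "phenylene")

pk_assemble_smiles <- function(family, donor, bridge, acceptor) {
  if (family == "chain") paste0(donor, bridge, acceptor)
  else paste0(donor, "c1ccc(", bridge, acceptor, ")cc1")
}

#' Default solvent palette with planted polarity indices
#'
#' Water, methanol, acetonitrile, dimethyl sulfoxide, and toluene with
#' polarity indices in \[0, 1\]. These are generator parameters used by the
#' planted solvatochromic rule, not measured polarities.
#'
#' @return Named numeric vector: names are solvent SMILES, values polarity.
#' @export
default_solvent_palette <- function() {
  c("O" = 1.0, "CO" = 0.76, "CC#N" = 0.46, "CS(C)=O" = 0.44,
    "Cc1ccccc1" = 0.10)
}

#' Default per-property measurement noise (generator)
#' @return Named numeric vector of Gaussian standard deviations.
#' @export
default_noise_sd <- function() {
  c(abs_wavelength = 5, em_wavelength = 5, abs_fwhm = 2, em_fwhm = 2,
    log10_eps = 0.02, plqy = 0.02, lifetime = 0.2)
}

#' Specification for the synthetic fluorophore generator
#'
#' Molecules are donor-bridge-acceptor chromophores assembled from a fixed,
#' unit-tested template set (three donors x three acceptors x two backbone
#' families) with a polyene bridge of length `L` and random methyl
#' decorations. The planted ground-truth rules (all constants exposed here)
#' are:
#' \deqn{\lambda_{abs} = 300 + 25L + 35D + 35A + 10P}
#' \deqn{\lambda_{em} = \lambda_{abs} + 40 + 8P}
#' \deqn{\log_{10}\epsilon = 4 + 0.1L}
#' \deqn{\Phi = \mathrm{logistic}(1.5 - 0.5R + 0.3L)}
#' \deqn{\tau = 1 + 4\Phi, \quad \mathrm{FWHM} = 40 + 6R}
#' with D/A the donor/acceptor strengths, P the solvent polarity index, and
#' R the rotatable-bond count of the assembled structure. Measurements add
#' Gaussian noise per property; the activity label is 1 iff both
#' wavelengths fall within `half_width` of the query window and the true
#' quantum yield is at least 0.05.
#'
#' @param n Library size (number of molecule draws).
#' @param seed Integer seed.
#' @param bridge_length_range Integer range of the polyene length L.
#' @param solvent_palette Named polarity map, see
#'   [default_solvent_palette()].
#' @param noise_sd Named per-property noise, see [default_noise_sd()].
#' @param label_window `c(abs, em, half_width)` in nm.
#' @param inconsistency_rate Fraction of molecules receiving an extra
#'   replicate offset beyond the curation tolerance (exercises curation).
#' @param measured_solvents How many palette solvents each molecule is
#'   "measured" in.
#' @param decoration_prob Probability of a methyl decoration per bridge
#'   unit.
#' @param phenylene_fraction Fraction of draws using the phenylene backbone.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n = 2000, seed = 1,
                           bridge_length_range = c(0L, 4L),
                           solvent_palette = default_solvent_palette(),
                           noise_sd = default_noise_sd(),
                           label_window = c(abs = 370, em = 420, half_width = 60),
                           inconsistency_rate = 0.05,
                           measured_solvents = 1L,
                           decoration_prob = 0.3,
                           phenylene_fraction = 0.25) {
  stopifnot(inconsistency_rate >= 0, inconsistency_rate <= 1,
            decoration_prob >= 0, decoration_prob <= 1,
            measured_solvents >= 1,
            measured_solvents <= length(solvent_palette))
  structure(
    list(n = n, seed = seed,
         bridge_length_range = as.integer(bridge_length_range),
         solvent_palette = solvent_palette, noise_sd = noise_sd,
         label_window = label_window,
         inconsistency_rate = inconsistency_rate,
         measured_solvents = as.integer(measured_solvents),
         decoration_prob = decoration_prob,
         phenylene_fraction = phenylene_fraction),
    class = "generator_spec"
  )
}

# Rotatable bonds: non-ring single bonds whose two atoms both have heavy
# degree >= 2.
pk_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0) return(0L)
  deg <- tabulate(c(b$a1, b$a2), nbins = nrow(mol$atoms))
  sum(b$order == 1 & !b$aromatic & !b$in_ring &
        deg[b$a1] >= 2 & deg[b$a2] >= 2)
}

# Planted deterministic property rules (no noise).
pk_true_properties <- function(L, D, A, R, P) {
  lambda_abs <- 300 + 25 * L + 35 * D + 35 * A + 10 * P
  lambda_em <- lambda_abs + 40 + 8 * P
  plqy <- stats::plogis(1.5 - 0.5 * R + 0.3 * L)
  tibble(
    abs_wavelength = lambda_abs,
    em_wavelength = lambda_em,
    log10_eps = 4 + 0.1 * L,
    plqy = plqy,
    lifetime = 1 + 4 * plqy,
    abs_fwhm = 40 + 6 * R,
    em_fwhm = 40 + 6 * R
  )
}

#' Generate a synthetic fluorophore library
#'
#' Draws `spec$n` molecules from the template grammar, computes their true
#' photophysical properties from the planted rules, emits noisy per-solvent
#' measurement records plus a wavelength-window activity label per
#' molecule, and (at `spec$inconsistency_rate`) injects extra replicates
#' that violate the curation tolerance.
#'
#' @param spec A [generator_spec()].
#' @return List with `records` (long measurement tibble: `molecule_id`,
#'   `smiles`, `solvent_smiles`, `property`, `value`, `injected_inconsistency`),
#'   `molecules` (per-draw tibble: `molecule_id`, `smiles`, `label`,
#'   `abs_query`, `em_query`, planted `L`, `D`, `A`, `R`), and `truth`
#'   (per-draw, per-palette-solvent true values of the seven properties).
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$n == 0) {
    return(list(
      records = tibble(molecule_id = integer(0), smiles = character(0),
                       solvent_smiles = character(0), property = character(0),
                       value = numeric(0), injected_inconsistency = logical(0)),
      molecules = tibble(molecule_id = integer(0), smiles = character(0),
                         label = numeric(0)),
      truth = tibble(molecule_id = integer(0))
    ))
  }
  pk_with_seed(spec$seed, {
    n <- spec$n
    Lr <- spec$bridge_length_range
    L <- sample(Lr[1]:Lr[2], n, replace = TRUE)
    di <- sample(nrow(PK_DONORS), n, replace = TRUE)
    ai <- sample(nrow(PK_ACCEPTORS), n, replace = TRUE)
    fam <- ifelse(stats::runif(n) < spec$phenylene_fraction,
                  "phenylene", "chain")
    smiles <- character(n)
    R <- integer(n)
    for (i in seq_len(n)) {
      units <- if (L[i] > 0) {
        ifelse(stats::runif(L[i]) < spec$decoration_prob, "C(C)=C", "C=C")
      } else character(0)
      smi <- pk_assemble_smiles(fam[i], PK_DONORS$donor_smiles[di[i]],
                                paste(units, collapse = ""),
                                PK_ACCEPTORS$acceptor_smiles[ai[i]])
      smiles[i] <- smi
    }
    canon <- canonicalize_smiles(smiles)
    ucanon <- unique(canon)
    uR <- vapply(ucanon, function(s) pk_rotatable_bonds(pk_parse_mol(s)),
                 integer(1))
    R <- unname(uR[match(canon, ucanon)])

    D <- PK_DONORS$donor_strength[di]
    A <- PK_ACCEPTORS$acceptor_strength[ai]
    palette <- spec$solvent_palette

    # Full per-solvent ground truth.
    truth <- tidyr::crossing(
      molecule_id = seq_len(n),
      solvent_smiles = names(palette)
    )
    truth$polarity <- palette[truth$solvent_smiles]
    tp <- pk_true_properties(L[truth$molecule_id], D[truth$molecule_id],
                             A[truth$molecule_id], R[truth$molecule_id],
                             truth$polarity)
    truth <- dplyr::bind_cols(truth, tp)

    # Activity label from the true values in the palette's reference
    # solvent (the least polar, P closest to 0, as a neutral baseline is
    # not in the palette) -- use polarity-0 values for the window rule.
    base <- pk_true_properties(L, D, A, R, 0)
    win <- spec$label_window
    label <- as.numeric(
      abs(base$abs_wavelength - win[["abs"]]) <= win[["half_width"]] &
        abs(base$em_wavelength - win[["em"]]) <= win[["half_width"]] &
        base$plqy >= 0.05
    )
    molecules <- tibble(
      molecule_id = seq_len(n), smiles = canon, label = label,
      abs_query = unname(win[["abs"]]), em_query = unname(win[["em"]]),
      L = L, D = D, A = A, R = R, family = fam
    )

    # Noisy measurement records in a sampled subset of solvents.
    props <- pk_properties()
    k <- spec$measured_solvents
    sel <- tibble(
      molecule_id = rep(seq_len(n), each = k),
      solvent_smiles = unlist(lapply(seq_len(n), function(i) {
        sample(names(palette), k)
      }))
    )
    picked <- dplyr::inner_join(truth, sel,
                                by = c("molecule_id", "solvent_smiles"))
    records <- tidyr::pivot_longer(
      picked[, c("molecule_id", "solvent_smiles", props)],
      dplyr::all_of(props), names_to = "property", values_to = "value"
    )
    records$value <- records$value +
      stats::rnorm(nrow(records), 0, spec$noise_sd[records$property])
    records$smiles <- canon[records$molecule_id]
    records$injected_inconsistency <- FALSE

    # Deliberate replicate inconsistencies (exceed the curation tolerance).
    n_bad <- round(spec$inconsistency_rate * n)
    if (n_bad > 0) {
      bad_ids <- sample(n, n_bad)
      bad <- records |>
        dplyr::filter(.data$molecule_id %in% bad_ids,
                      .data$property == "abs_wavelength") |>
        dplyr::group_by(.data$molecule_id) |>
        dplyr::slice(1) |>
        dplyr::ungroup()
      bad$value <- bad$value + 25  # 5x the 5 nm wavelength tolerance
      bad$injected_inconsistency <- TRUE
      records <- dplyr::bind_rows(records, bad)
    }
    records <- records[, c("molecule_id", "smiles", "solvent_smiles",
                           "property", "value", "injected_inconsistency")]
    list(records = records, molecules = molecules, truth = truth)
  })
}

#' Classification training frame from a synthetic library
#' @param library Output of [generate_library()].
#' @return Tibble with `smiles`, `label`, `abs_query`, `em_query`.
#' @export
classification_frame <- function(library) {
  dplyr::select(library$molecules, "smiles", "label", "abs_query", "em_query")
}

#' Regression training frame from a synthetic library
#' @param library Output of [generate_library()].
#' @param property One of [pk_properties()].
#' @param from_truth Use noiseless true values instead of noisy records.
#' @return Tibble with `smiles`, `solvent_smiles`, `value`.
#' @export
regression_frame <- function(library, property = "em_wavelength",
                             from_truth = FALSE) {
  property <- match.arg(property, pk_properties())
  if (from_truth) {
    sub <- library$truth
    out <- tibble(
      smiles = library$molecules$smiles[sub$molecule_id],
      solvent_smiles = canonicalize_smiles(sub$solvent_smiles),
      value = sub[[property]]
    )
    return(out)
  }
  sub <- dplyr::filter(library$records, .data$property == !!property,
                       !.data$injected_inconsistency)
  tibble(
    smiles = sub$smiles,
    solvent_smiles = canonicalize_smiles(sub$solvent_smiles),
    value = sub$value
  )
}

#' Default saturation-binding titration grid (nM)
#'
#' The fourteen-point probe titration used for dissociation-constant
#' measurements: 0 to 1000 nM.
#' @return Numeric vector of concentrations in nM.
#' @export
default_titration_grid <- function() {
  c(0, 1, 2, 5, 8, 10, 20, 50, 80, 100, 200, 500, 800, 1000)
}

#' Generate a synthetic assay series
#'
#' Evaluates the closed-form assay model on a grid and adds seeded Gaussian
#' intensity noise: `"fh"` is the log-log viscosity response
#' `I = 10^(C + x log10 eta)`; `"kd"` the one-site saturation binding
#' `I = F0 + Bmax x/(Kd + x)`; `"hill"` its Hill generalization with
#' exponent `h`.
#'
#' @param kind `"fh"`, `"kd"`, or `"hill"`.
#' @param params Named list of model parameters (`C`, `x` for `"fh"`;
#'   `F0`, `Bmax`, `Kd`, and `h` for `"hill"`).
#' @param grid x-axis values (viscosity in cP or concentration in nM);
#'   defaults to [default_titration_grid()] for binding kinds.
#' @param noise_sd Gaussian intensity noise (absolute units).
#' @param seed Integer seed.
#' @return Tibble with `x` and `intensity`.
#' @export
generate_assay_curves <- function(kind = c("fh", "kd", "hill"), params,
                                  grid = NULL, noise_sd = 0, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- if (kind == "fh") c(1, 2, 5, 10, 50, 100)
            else default_titration_grid()
  }
  mu <- switch(kind,
    fh = 10^(params$C + params$x * log10(grid)),
    kd = params$F0 + params$Bmax * grid / (params$Kd + grid),
    hill = params$F0 + params$Bmax * grid^params$h /
      (params$Kd^params$h + grid^params$h)
  )
  if (kind == "hill") mu[grid == 0] <- params$F0
  pk_with_seed(seed, {
    tibble(x = grid, intensity = mu + stats::rnorm(length(grid), 0, noise_sd))
  })
}

#' Generate two structurally distinct scaffold families
#'
#' Produces decorated members of two structurally disjoint ring families
#' (an aromatic biaryl and a saturated aza-heterocycle) whose fingerprints
#' separate in chemical space; used to exercise scaffold and embedding
#' analyses.
#'
#' @param n_per_family Members per family.
#' @param seed Integer seed.
#' @return Tibble with `smiles` and `family`.
#' @export
generate_scaffold_families <- function(n_per_family = 30, seed = 42) {
  decorations <- c("C", "CC", "CCC", "CO", "CN(C)", "CCO", "CCC(C)")
  build <- c(biphenyl = "%sc1ccc(-c2ccccc2)cc1",
             piperidine = "%sC1CCN(CC1)C")
  pk_with_seed(seed, {
    out <- lapply(names(build), function(fam) {
      dec <- sample(decorations, n_per_family, replace = TRUE)
      tibble(smiles = sprintf(build[[fam]], dec), family = fam)
    })
    df <- dplyr::bind_rows(out)
    df$smiles <- canonicalize_smiles(df$smiles)
    df
  })
}
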