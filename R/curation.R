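#' Label a fluorescence activity score
#'
#' PubChem-style assay scores on the 0-100 scale are dichotomized at a
#' threshold of 20 by default; scores at or above the threshold are
#' labeled fluorescent (the boundary is inclusive, configurable via
#' `inclusive`).
#'
#' @param score Numeric vector of activity scores in \[0, 100\].
#' @param threshold Cut point on the score scale (default 20).
#' @param inclusive Should `score == threshold` count as fluorescent?
#' @return Character vector, `"fluorescent"` or `"non-fluorescent"`.
#' @examples
#' label_from_score(c(0, 20, 100))
#' @export
label_from_score <- function(score, threshold = 20, inclusive = TRUE) {
  stopifnot(is.numeric(score))
  if (any(!is.na(score) & (score < 0 | score > 100))) {
    abort("activity scores must lie in [0, 100]", class = "probekit_domain_error")
  }
  hit <- if (inclusive) score >= threshold else score > threshold
  ifelse(hit, "fluorescent", "non-fluorescent")
}

pk_default_tolerances <- function() {
  c(abs_wavelength = 5, em_wavelength = 5, plqy = 0.1, log10_eps = 0.02,
    abs_fwhm = Inf, em_fwhm = Inf, lifetime = Inf)
}

#' Default replicate-consistency tolerances
#'
#' 5 nm for absorption/emission wavelengths, 0.1 for quantum yield, 0.02
#' for log10 molar absorptivity; FWHMs and lifetime carry no consistency
#' filter by default (infinite tolerance).
#'
#' @return Named numeric vector keyed by property.
#' @export
default_tolerances <- pk_default_tolerances

pk_audit_row <- function(stage, rule, n) tibble(stage = stage, rule = rule, n = n)

#' Deduplicate records and resolve label conflicts
#'
#' For classification data, records identical in (canonical SMILES, test
#' condition, label) are merged into one; any structure annotated with both
#' labels across records is removed entirely. For regression data, exact
#' duplicate measurement rows are merged (replicate handling is done by
#' [filter_measurements()]).
#'
#' @param records Tibble with canonical `smiles`; classification rows carry
#'   `label` (and optional `abs_query`/`em_query` test conditions),
#'   regression rows carry `solvent_smiles`, `property`, `value`.
#' @param task `"classification"` or `"regression"`.
#' @return List with `records` (curated tibble) and `audit` (tibble of
#'   per-rule counts; dropped + retained sums to the input count).
#' @export
deduplicate_and_resolve <- function(records,
                                    task = c("classification", "regression")) {
  task <- match.arg(task)
  n_in <- nrow(records)
  if (n_in == 0) {
    return(list(records = records,
                audit = pk_audit_row("deduplicate", c("duplicate_merged",
                  "conflicting_label", "retained"), c(0, 0, 0))))
  }
  df <- records
  if (task == "classification") {
    for (col in c("abs_query", "em_query")) {
      if (!col %in% names(df)) df[[col]] <- NA_real_
    }
    keys <- c("smiles", "abs_query", "em_query", "label")
    merged <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    n_merged_away <- n_in - nrow(merged)
    conflict_smiles <- merged |>
      dplyr::distinct(.data$smiles, .data$label) |>
      dplyr::count(.data$smiles) |>
      dplyr::filter(.data$n > 1) |>
      dplyr::pull(.data$smiles)
    out <- dplyr::filter(merged, !.data$smiles %in% conflict_smiles)
    n_conflict <- nrow(merged) - nrow(out)
  } else {
    keys <- intersect(c("smiles", "solvent_smiles", "property", "value"),
                      names(df))
    out <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    n_merged_away <- n_in - nrow(out)
    n_conflict <- 0L
  }
  audit <- pk_audit_row(
    "deduplicate",
    c("duplicate_merged", "conflicting_label", "retained"),
    c(n_merged_away, n_conflict, nrow(out))
  )
  list(records = out, audit = audit)
}

pk_gaseous_sentinels <- function() c("", "gas", "gas phase", "null", "na")

#' Filter and consolidate photophysical measurements
#'
#' Applies, in order: solvent screening (missing, sentinel-gaseous, or
#' unparsable solvent entries are dropped), physical range filters
#' (quantum yield in \[0, 1\], wavelengths in \[200, 1500\] nm, log10 molar
#' absorptivity at most 7, positive FWHM/lifetime), and replicate
#' consolidation per (structure, solvent, property) group: entries deviating
#' from the group median by more than the property's tolerance are dropped
#' as inconsistent, the survivors are arithmetically averaged into a single
#' measurement.
#'
#' @param records Tibble of measurement rows: `smiles`, `solvent_smiles`,
#'   `property` (one of [pk_properties()]), `value`.
#' @param tolerances Named numeric vector of per-property tolerances; see
#'   [default_tolerances()]. Unknown property names raise a configuration
#'   error.
#' @param gaseous_sentinels Strings treated as missing/gaseous solvent.
#' @return List with `records` and `audit` (as in
#'   [deduplicate_and_resolve()]).
#' @export
filter_measurements <- function(records, tolerances = default_tolerances(),
                                gaseous_sentinels = pk_gaseous_sentinels()) {
  unknown <- setdiff(names(tolerances), pk_properties())
  if (length(unknown)) {
    abort(paste0("unknown property in tolerances: ",
                 paste(unknown, collapse = ", ")),
          class = "probekit_config_error")
  }
  tol <- pk_default_tolerances()
  tol[names(tolerances)] <- tolerances

  df <- records
  n_in <- nrow(df)
  empty_audit <- function(ret) pk_audit_row(
    "filter_measurements",
    c("missing_or_gaseous_solvent", "invalid_solvent", "range_filter",
      "replicate_inconsistency", "replicate_averaged", "retained"),
    ret
  )
  if (n_in == 0) return(list(records = df, audit = empty_audit(rep(0, 6))))

  solv <- tolower(trimws(ifelse(is.na(df$solvent_smiles), "",
                                df$solvent_smiles)))
  gaseous <- solv %in% tolower(gaseous_sentinels)
  n_gas <- sum(gaseous)
  df <- df[!gaseous, , drop = FALSE]

  valid_solv <- is_valid_smiles(as.character(df$solvent_smiles))
  n_invalid_solv <- sum(!valid_solv)
  df <- df[valid_solv, , drop = FALSE]

  in_range <- with(df, dplyr::case_when(
    property == "plqy" ~ value >= 0 & value <= 1,
    property %in% c("abs_wavelength", "em_wavelength") ~
      value >= 200 & value <= 1500,
    property == "log10_eps" ~ value <= 7,
    property %in% c("abs_fwhm", "em_fwhm", "lifetime") ~ value > 0,
    TRUE ~ TRUE
  ))
  n_range <- sum(!in_range)
  df <- df[in_range, , drop = FALSE]

  # Replicate groups: median +/- tolerance, then average the survivors.
  n_outlier <- 0L
  n_averaged_away <- 0L
  if (nrow(df) > 0) {
    df$solvent_smiles <- canonicalize_smiles(df$solvent_smiles)
    grp <- paste(df$smiles, df$solvent_smiles, df$property, sep = "|")
    keep_rows <- logical(nrow(df))
    pieces <- split(seq_len(nrow(df)), grp)
    out_rows <- vector("list", length(pieces))
    for (k in seq_along(pieces)) {
      ix <- pieces[[k]]
      v <- df$value[ix]
      t_k <- tol[[df$property[ix[1]]]]
      ok <- abs(v - stats::median(v)) <= t_k
      n_outlier <- n_outlier + sum(!ok)
      if (any(ok)) {
        row <- df[ix[which(ok)[1]], , drop = FALSE]
        row$value <- mean(v[ok])
        n_averaged_away <- n_averaged_away + sum(ok) - 1L
        out_rows[[k]] <- row
      }
    }
    df <- dplyr::bind_rows(out_rows)
  }

  audit <- empty_audit(c(n_gas, n_invalid_solv, n_range, n_outlier,
                         n_averaged_away, nrow(df)))
  list(records = df, audit = audit)
}

#' Curate a raw molecule table end to end
#'
#' Canonicalizes structures (dropping unparsable SMILES), derives labels
#' from activity scores where missing, merges duplicates, removes
#' label conflicts, and (for regression data) applies the measurement
#' filters of [filter_measurements()].
#'
#' @param data Tibble with column `smiles`; optional `score`, `label`,
#'   `abs_query`, `em_query`, `solvent_smiles`, `property`, `value`.
#' @param task `"classification"` or `"regression"`.
#' @param threshold Activity-score labeling threshold (classification).
#' @param tolerances Passed to [filter_measurements()].
#' @param gaseous_sentinels Passed to [filter_measurements()].
#' @return List with `records` (curated tibble, canonical `smiles`) and
#'   `audit` (tibble of per-stage, per-rule counts).
#' @export
curate_dataset <- function(data, task = c("classification", "regression"),
                           threshold = 20,
                           tolerances = default_tolerances(),
                           gaseous_sentinels = pk_gaseous_sentinels()) {
  task <- match.arg(task)
  stopifnot("smiles" %in% names(data))
  df <- tibble::as_tibble(data)
  # CSV round-trips leave empty strings where values are missing
  for (col in c("label", "property")) {
    if (col %in% names(df) && is.character(df[[col]])) {
      df[[col]][!nzchar(df[[col]])] <- NA_character_
    }
  }
  n_in <- nrow(df)

  canon <- canonicalize_smiles(df$smiles, strict = FALSE)
  n_invalid <- sum(is.na(canon))
  df$smiles <- canon
  df <- df[!is.na(canon), , drop = FALSE]
  audit <- pk_audit_row("canonicalize", c("invalid_smiles", "retained"),
                        c(n_invalid, nrow(df)))

  if (task == "classification") {
    if (!"label" %in% names(df)) df$label <- NA_character_
    needs <- is.na(df$label) & !is.na(df$score %||% rep(NA_real_, nrow(df)))
    if ("score" %in% names(df) && any(needs)) {
      df$label[needs] <- label_from_score(df$score[needs], threshold)
    }
    n_unlabeled <- sum(is.na(df$label))
    df <- df[!is.na(df$label), , drop = FALSE]
    audit <- dplyr::bind_rows(
      audit,
      pk_audit_row("label", c("unlabeled", "retained"),
                   c(n_unlabeled, nrow(df)))
    )
    dd <- deduplicate_and_resolve(df, task)
    audit <- dplyr::bind_rows(audit, dd$audit)
    df <- dd$records
  } else {
    if (!"property" %in% names(df)) df$property <- NA_character_
    n_nomeas <- sum(is.na(df$property))
    df <- df[!is.na(df$property), , drop = FALSE]
    audit <- dplyr::bind_rows(
      audit,
      pk_audit_row("measurements", c("no_measurement", "retained"),
                   c(n_nomeas, nrow(df)))
    )
    dd <- deduplicate_and_resolve(df, task)
    audit <- dplyr::bind_rows(audit, dd$audit)
    fm <- filter_measurements(dd$records, tolerances, gaseous_sentinels)
    audit <- dplyr::bind_rows(audit, fm$audit)
    df <- fm$records
  }
  list(records = df, audit = audit)
}

#' Assign train/validation/test splits
#'
#' Random partition at the stated ratios (default 7:1:2). Validation and
#' test sizes are `floor(n * ratio)`; the remainder goes to train. The
#' partition is exhaustive, disjoint, and deterministic given `seed`.
#'
#' @param data Tibble of records.
#' @param ratios Length-3 numeric (train, val, test) summing to 1.
#' @param seed Integer seed.
#' @param by `"record"` (default) or `"molecule"` — the latter keeps all
#'   rows of one structure in the same split to avoid condition leakage.
#' @return `data` with a `split` column (`"train"`, `"val"`, `"test"`).
#' @export
split_dataset <- function(data, ratios = c(0.7, 0.1, 0.2), seed = 0,
                          by = c("record", "molecule")) {
  by <- match.arg(by)
  if (any(ratios < 0)) abort("ratios must be non-negative",
                             class = "probekit_domain_error")
  if (abs(sum(ratios) - 1) > 1e-9) abort("ratios must sum to 1",
                                         class = "probekit_domain_error")
  units <- if (by == "molecule") unique(data$smiles) else seq_len(nrow(data))
  n <- length(units)
  n_val <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ord <- sample.int(n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  assignment <- rep("train", n)
  if (n_val > 0) assignment[ord[seq_len(n_val)]] <- "val"
  if (n_test > 0) assignment[ord[n_val + seq_len(n_test)]] <- "test"
  if (by == "molecule") {
    data$split <- assignment[match(data$smiles, units)]
  } else {
    data$split <- assignment
  }
  data
}
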