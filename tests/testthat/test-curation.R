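test_that("canonicalization maps spellings together, is idempotent, rejects garbage", {
  spellings <- canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(spellings[1], spellings[2])

  for (s in c("c1ccccc1", "CCO", "CC(=O)Oc1ccccc1C(=O)O")) {
    once <- canonicalize_smiles(s)
    expect_identical(canonicalize_smiles(once), once)
  }

  expect_error(canonicalize_smiles("C1CC"), class = "probekit_invalid_structure")
  expect_identical(canonicalize_smiles(c("CCO", "C1CC"), strict = FALSE),
                   c("CCO", NA))
  expect_identical(is_valid_smiles(c("CCO", "xyz")), c(TRUE, FALSE))
})

test_that("score labeling uses an inclusive threshold of 20 and rejects out-of-range scores", {
  expect_identical(label_from_score(c(0, 19.99, 20, 100)),
                   c("non-fluorescent", "non-fluorescent",
                     "fluorescent", "fluorescent"))
  expect_identical(label_from_score(20, inclusive = FALSE), "non-fluorescent")
  expect_identical(label_from_score(50, threshold = 60), "non-fluorescent")
  expect_error(label_from_score(120), class = "probekit_domain_error")
  expect_error(label_from_score(-1), class = "probekit_domain_error")
})

test_that("duplicates merge and conflicting labels remove the structure entirely", {
  recs <- tibble::tibble(
    smiles = c("Cc1ccccc1", "Cc1ccccc1", "CCO", "CCO"),
    label = c("fluorescent", "fluorescent", "fluorescent", "non-fluorescent"),
    abs_query = 370, em_query = 440
  )
  out <- deduplicate_and_resolve(recs, "classification")
  expect_identical(out$records$smiles, "Cc1ccccc1")
  audit <- out$audit
  expect_equal(audit$n[audit$rule == "duplicate_merged"], 1)
  expect_equal(audit$n[audit$rule == "conflicting_label"], 2)
  expect_equal(sum(audit$n), nrow(recs))

  empty <- deduplicate_and_resolve(recs[0, ], "classification")
  expect_equal(nrow(empty$records), 0)
  expect_equal(sum(empty$audit$n), 0)
})

test_that("measurement filters drop out-of-range values and resolve replicates by median tolerance", {
  meas <- function(value, prop = "em_wavelength", solvent = "CCO") {
    tibble::tibble(smiles = "Cc1ccccc1", solvent_smiles = solvent,
                   property = prop, value = value)
  }
  # range violations
  dropped <- dplyr::bind_rows(
    meas(1.2, "plqy"), meas(1600, "abs_wavelength"), meas(7.5, "log10_eps")
  )
  out <- filter_measurements(dropped)
  expect_equal(nrow(out$records), 0)
  expect_equal(out$audit$n[out$audit$rule == "range_filter"], 3)

  # replicates within tolerance average; beyond tolerance are dropped
  avg <- filter_measurements(meas(c(500, 503)))
  expect_equal(avg$records$value, 501.5)
  expect_equal(nrow(avg$records), 1)

  incons <- filter_measurements(meas(c(500, 520)))
  expect_equal(nrow(incons$records), 0)
  expect_equal(incons$audit$n[incons$audit$rule == "replicate_inconsistency"], 2)

  mixed <- filter_measurements(meas(c(500, 503, 520)))
  expect_equal(mixed$records$value, 501.5)
  expect_equal(mixed$audit$n[mixed$audit$rule == "replicate_inconsistency"], 1)

  # solvent screening
  gas <- filter_measurements(meas(500, solvent = "gas"))
  expect_equal(nrow(gas$records), 0)
  missing <- filter_measurements(meas(500, solvent = NA))
  expect_equal(nrow(missing$records), 0)

  expect_error(filter_measurements(meas(500), tolerances = c(bogus = 1)),
               class = "probekit_config_error")
})

test_that("curation stages are idempotent, order-invariant, and conserve counts", {
  lib <- generate_library(generator_spec(n = 60, seed = 5,
                                         inconsistency_rate = 0.2,
                                         measured_solvents = 2))
  rf <- regression_frame(lib, "em_wavelength")
  rf$property <- "em_wavelength"
  rf <- dplyr::bind_rows(
    rf,
    dplyr::mutate(lib$records[lib$records$injected_inconsistency,
                              c("smiles", "solvent_smiles", "property", "value")],
                  solvent_smiles = canonicalize_smiles(solvent_smiles))
  )
  out1 <- filter_measurements(rf)
  # idempotence
  out2 <- filter_measurements(out1$records)
  expect_equal(dplyr::arrange(out2$records, smiles, solvent_smiles),
               dplyr::arrange(out1$records, smiles, solvent_smiles))
  # conservation
  dropped <- sum(out1$audit$n[out1$audit$rule != "retained"])
  expect_equal(dropped + nrow(out1$records), nrow(rf))
  # order invariance
  shuf <- rf[probekit:::pk_with_seed(9, sample.int(nrow(rf))), ]
  out3 <- filter_measurements(shuf)
  expect_equal(dplyr::arrange(out3$records, smiles, solvent_smiles, property),
               dplyr::arrange(out1$records, smiles, solvent_smiles, property))
})

test_that("splits honour floor arithmetic, determinism, and degenerate ratios", {
  df <- tibble::tibble(smiles = paste0("id", 1:100))
  s1 <- split_dataset(df, seed = 0)
  expect_equal(unname(table(s1$split)[c("train", "val", "test")]),
               c(70, 10, 20), ignore_attr = TRUE)
  s2 <- split_dataset(df, seed = 0)
  expect_identical(s1$split, s2$split)
  expect_false(identical(s1$split, split_dataset(df, seed = 1)$split))

  all_train <- split_dataset(df[1:10, ], ratios = c(1, 0, 0), seed = 3)
  expect_true(all(all_train$split == "train"))

  expect_error(split_dataset(df, ratios = c(-0.1, 0.6, 0.5)),
               class = "probekit_domain_error")
  expect_error(split_dataset(df, ratios = c(0.5, 0.2, 0.2)),
               class = "probekit_domain_error")

  # molecule-level split keeps repeated structures together
  rep_df <- tibble::tibble(smiles = rep(paste0("m", 1:20), each = 3))
  sm <- split_dataset(rep_df, seed = 2, by = "molecule")
  per_mol <- tapply(sm$split, sm$smiles, function(x) length(unique(x)))
  expect_true(all(per_mol == 1))
})

test_that("the packaged curation fixture survives exactly as enumerated", {
  path <- system.file("extdata", "curation_fixture.csv", package = "probekit")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = list(solvent_smiles = "character",
                                           label = "character",
                                           property = "character"))
  toluene <- canonicalize_smiles("Cc1ccccc1")

  cls <- curate_dataset(raw, "classification")
  expect_identical(cls$records$smiles, toluene)
  a <- cls$audit
  expect_equal(a$n[a$stage == "canonicalize" & a$rule == "invalid_smiles"], 1)
  expect_equal(a$n[a$stage == "label" & a$rule == "unlabeled"], 7)
  expect_equal(a$n[a$rule == "duplicate_merged"], 1)
  expect_equal(a$n[a$rule == "conflicting_label"], 2)
  expect_equal(a$n[a$stage == "deduplicate" & a$rule == "retained"], 1)

  reg <- curate_dataset(raw, "regression")
  expect_equal(nrow(reg$records), 1)
  expect_identical(reg$records$smiles, toluene)
  expect_identical(reg$records$property, "em_wavelength")
  expect_equal(reg$records$value, 501.5)
  b <- reg$audit
  expect_equal(b$n[b$rule == "no_measurement"], 3)
  expect_equal(b$n[b$rule == "missing_or_gaseous_solvent"], 2)
  expect_equal(b$n[b$rule == "range_filter"], 3)
  expect_equal(b$n[b$rule == "replicate_inconsistency"], 1)
  expect_equal(b$n[b$rule == "replicate_averaged"], 1)
  # per-stage conservation
  for (st in unique(b$stage)) {
    sub <- b[b$stage == st, ]
    expect_gte(sub$n[sub$rule == "retained"], 0)
  }
})
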