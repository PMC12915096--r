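# Known configuration keys with their defaults; unknown keys are rejected.
pk_config_defaults <- function() {
  list(
    seed = 1L,
    synthetic = list(n = 2000L, measured_solvents = 1L,
                     inconsistency_rate = 0.05),
    curation = list(threshold = 20, task = "classification"),
    split = list(ratios = c(0.7, 0.1, 0.2)),
    classifier = list(epochs = 30L, init_lr = 1e-4, hidden = 300L,
                      depth = 3L, batch_size = 64L),
    regressors = list(properties = "em_wavelength", epochs = 50L,
                      init_lr = 1e-3, hidden = 300L, depth = 3L,
                      batch_size = 64L),
    screening = list(abs_nm = 370, em_nm = 420, solvent = "CC#N",
                     threshold = 0.5),
    chemspace = list(perplexity = 30, seed = 42L, top_scaffolds = 20L),
    paths = list(input = NULL, output_dir = NULL)
  )
}

pk_merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      abort(paste0("unknown configuration key: ", full),
            class = "probekit_config_error")
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- pk_merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills documented defaults, and rejects
#' unknown keys (naming the offending key).
#'
#' @param path Path to a YAML file, or a named list.
#' @return A validated `pipeline_config` list.
#' @export
load_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) {
      abort(paste0("configuration file not found: ", path),
            class = "probekit_config_error")
    }
    yaml::read_yaml(path)
  } else {
    path
  }
  cfg <- pk_merge_config(pk_config_defaults(), user %||% list())
  structure(cfg, class = "pipeline_config")
}

# Derive a reproducible per-stage seed from the global seed (kept below
# 2^31 so it is always a valid R integer).
pk_stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L +
     sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))) %% 2147483629L
}

#' Run the end-to-end discovery pipeline on synthetic data
#'
#' Orchestrates curate -> split -> train classifier -> train regressors ->
#' two-step screen -> chemical-space analysis on a generated fluorophore
#' library, and returns a manifest describing every stage.
#'
#' @param config A `pipeline_config` from [load_config()] (or a list
#'   accepted by it).
#' @param verbose Print stage progress.
#' @return List with `manifest` (tibble: stage, status, detail), the fitted
#'   models, the screening table, and the chemspace result.
#' @export
run_pipeline <- function(config = load_config(list()), verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- load_config(config)
  stages <- character(0)
  note <- function(stage, detail) {
    if (verbose) cat("[", stage, "] ", detail, "\n", sep = "")
    stages <<- c(stages, stage)
    tibble(stage = stage, detail = detail)
  }
  manifest <- list()

  gspec <- generator_spec(
    n = config$synthetic$n,
    seed = pk_stage_seed(config$seed, "generate"),
    measured_solvents = config$synthetic$measured_solvents,
    inconsistency_rate = config$synthetic$inconsistency_rate
  )
  lib <- generate_library(gspec)
  manifest$generate <- note("generate", paste(nrow(lib$molecules), "molecules"))

  cls_cur <- curate_dataset(classification_frame(lib), "classification",
                            threshold = config$curation$threshold)
  reg_raw <- regression_frame(lib, config$regressors$properties[1])
  reg_raw$property <- config$regressors$properties[1]
  reg_cur <- curate_dataset(reg_raw, "regression")
  manifest$curate <- note("curate", paste(nrow(cls_cur$records),
                                          "classification records,",
                                          nrow(reg_cur$records),
                                          "regression records"))

  cls <- split_dataset(cls_cur$records, config$split$ratios,
                       seed = pk_stage_seed(config$seed, "split"))
  reg <- split_dataset(reg_cur$records, config$split$ratios,
                       seed = pk_stage_seed(config$seed, "split-reg"))
  manifest$split <- note("split", paste(sum(cls$split == "train"), "train /",
                                        sum(cls$split == "val"), "val /",
                                        sum(cls$split == "test"), "test"))

  l1_cfg <- encoder_config(
    "classification", depth = config$classifier$depth,
    hidden = config$classifier$hidden, epochs = config$classifier$epochs,
    init_lr = config$classifier$init_lr,
    batch_size = config$classifier$batch_size,
    seed = pk_stage_seed(config$seed, "train-l1")
  )
  l1 <- train_model(dplyr::filter(cls, .data$split == "train"),
                    dplyr::filter(cls, .data$split == "val"), l1_cfg)
  manifest$train_l1 <- note("train_l1",
                            paste("best val AUC",
                                  signif(max(l1$history$val_metric), 4)))

  l2 <- list()
  for (prop in config$regressors$properties) {
    reg_p <- dplyr::rename(reg, value = "value")
    l2_cfg <- encoder_config(
      "regression", target_property = prop,
      depth = config$regressors$depth, hidden = config$regressors$hidden,
      epochs = config$regressors$epochs, init_lr = config$regressors$init_lr,
      batch_size = config$regressors$batch_size,
      seed = pk_stage_seed(config$seed, paste0("train-l2-", prop))
    )
    l2[[prop]] <- train_model(dplyr::filter(reg_p, .data$split == "train"),
                              dplyr::filter(reg_p, .data$split == "val"),
                              l2_cfg)
  }
  manifest$train_l2 <- note("train_l2", paste(length(l2), "regressor(s)"))

  test_lib <- dplyr::filter(cls, .data$split == "test")["smiles"]
  hits <- two_step_screen(
    test_lib, l1, l2,
    wavelength_pair = c(config$screening$abs_nm, config$screening$em_nm),
    solvent_smiles = config$screening$solvent,
    threshold = config$screening$threshold
  )
  manifest$screen <- note("screen", paste(sum(hits$passed_l1), "of",
                                          nrow(hits), "passed step 1"))

  surv <- dplyr::filter(hits, .data$passed_l1)
  cs <- NULL
  if (nrow(surv) >= 5) {
    cs <- chemspace_analysis(surv["smiles"],
                             perplexity = config$chemspace$perplexity,
                             seed = config$chemspace$seed,
                             top_k = config$chemspace$top_scaffolds)
  }
  manifest$chemspace <- note("chemspace",
                             if (is.null(cs)) "skipped (too few survivors)"
                             else paste(nrow(cs$coords), "molecules embedded"))

  list(
    manifest = dplyr::bind_rows(manifest),
    config = config,
    audits = list(classification = cls_cur$audit, regression = reg_cur$audit),
    l1_model = l1, l2_models = l2,
    hits = hits, chemspace = cs
  )
}
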