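test_that("vectorized encoder matches the loop-based oracle on tiny molecules", {
  sc <- small_seeded_cls()
  for (s in tiny_fixture_smiles()) {
    g <- featurize_molecule(s)
    emb <- encode_graph(g, sc$cfg, sc$params)
    expect_lt(max(abs(emb - oracle_encode(g, sc$params$encoder, sc$cfg$depth))),
              1e-6)
  }
})

test_that("encoder handles the no-bond and depth-zero cases by definition", {
  sc <- small_seeded_cls()
  g <- featurize_molecule("C")
  emb <- encode_graph(g, sc$cfg, sc$params)
  manual <- pmax(c(g$atom_features[1, ], numeric(sc$cfg$hidden)) %*%
                   sc$params$encoder$W_a, 0)
  expect_equal(emb, as.numeric(manual))

  sc0 <- small_seeded_cls(depth = 0L)
  g3 <- featurize_molecule("CCC")
  emb0 <- encode_graph(g3, sc0$cfg, sc0$params)
  expect_lt(max(abs(emb0 - oracle_encode(g3, sc0$params$encoder, 0))), 1e-6)
})

test_that("activity predictions are sigmoid outputs conditioned on the wavelength pair", {
  sc <- small_seeded_cls()
  g <- featurize_molecule("CC=CC#N")
  # zero final layer -> logit 0 -> score 0.5
  p0 <- sc$params
  L <- length(p0$ffn)
  p0$ffn[[L]]$W[] <- 0
  p0$ffn[[L]]$b[] <- 0
  expect_equal(predict_activity(g, c(370, 440), sc$cfg, p0), 0.5)

  s1 <- predict_activity(g, c(370, 440), sc$cfg, sc$params)
  expect_true(s1 >= 0 && s1 <= 1)
  expect_identical(s1, predict_activity(g, c(370, 440), sc$cfg, sc$params))
  # different condition generally moves the score
  s2 <- predict_activity(g, c(800, 1100), sc$cfg, sc$params)
  expect_false(identical(s1, s2))

  rg <- small_seeded_reg()
  expect_error(predict_activity(g, c(370, 440), rg$cfg, rg$params),
               class = "probekit_task_mismatch")
})

test_that("property predictions flow through the solvent branch and denormalize", {
  rg <- small_seeded_reg()
  g <- featurize_molecule("CC=CC#N")
  v_water <- predict_property(g, "O", rg$cfg, rg$params)
  v_tol <- predict_property(g, "Cc1ccccc1", rg$cfg, rg$params)
  expect_false(identical(v_water, v_tol))

  # zero FFN -> prediction equals the training-target mean
  pz <- rg$params
  pz$target_mean <- 512
  pz$target_sd <- 33
  for (l in seq_along(pz$ffn)) {
    pz$ffn[[l]]$W[] <- 0
    pz$ffn[[l]]$b[] <- 0
  }
  expect_equal(predict_property(g, "O", rg$cfg, pz), 512)

  expect_error(predict_property(g, "not a solvent", rg$cfg, rg$params),
               class = "probekit_invalid_structure")
  sc <- small_seeded_cls()
  expect_error(predict_property(g, "O", sc$cfg, sc$params),
               class = "probekit_task_mismatch")
})

test_that("full regression forward matches an end-to-end oracle on tiny molecules", {
  rg <- small_seeded_reg()
  rg$params$target_mean <- 450
  rg$params$target_sd <- 40
  g <- featurize_molecule("CC=O")
  sg <- featurize_molecule("CO")
  emb <- oracle_encode(g, rg$params$encoder, rg$cfg$depth)
  semb <- oracle_encode(sg, rg$params$solvent, rg$cfg$solvent_depth)
  manual <- oracle_ffn(matrix(c(emb, semb), 1), rg$params$ffn) * 40 + 450
  expect_equal(predict_property(g, "CO", rg$cfg, rg$params), manual,
               tolerance = 1e-10)
})

test_that("predictions are invariant to atom-order rewrites", {
  sc <- small_seeded_cls()
  lib <- generate_library(generator_spec(n = 20, seed = 23))
  for (i in seq_len(20)) {
    s <- lib$molecules$smiles[i]
    base <- predict_activity(featurize_molecule(s), c(370, 440),
                             sc$cfg, sc$params)
    for (seed in 1:5) {
      gp <- permuted_graph(s, seed)
      expect_lt(abs(predict_activity(gp, c(370, 440), sc$cfg, sc$params) -
                      base), 1e-5)
    }
  }
})

test_that("metrics: rank AUC, R-squared, and MAE behave as defined", {
  # worked pair-counting example: 3 of 4 pos/neg pairs concordant
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(oracle_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)

  probekit:::pk_with_seed(4, {
    scores <- stats::runif(60)
    labels <- stats::rbinom(60, 1, 0.4)
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
    # cross-check against an independent library implementation
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(auc_score(scores, labels),
                   as.numeric(pROC::auc(pROC::roc(
                     labels, scores, quiet = TRUE,
                     levels = c(0, 1), direction = "<"
                   ))))
    }
    # invariance under strictly monotone transforms
    expect_equal(auc_score(exp(3 * scores) + 1, labels),
                 auc_score(scores, labels))
    # ties get midrank credit
    expect_equal(auc_score(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  })

  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_error(auc_score(c(1, 2), c(1, 1)), class = "probekit_metric_error")

  truth <- c(3, 5, 9, 11)
  expect_equal(r_squared(truth, truth), 1)
  expect_equal(mae(truth, truth), 0)
  expect_lte(r_squared(rev(truth), truth), 1)
  ev <- evaluate_predictions(truth + 1, truth, "regression")
  expect_equal(ev$value[ev$metric == "mae"], 1)
})

test_that("training memorizes a single molecule and is seed-reproducible", {
  df <- tibble::tibble(smiles = "CC=CC#N", label = 1,
                       abs_query = 370, em_query = 440)
  cfg <- encoder_config("classification", hidden = 16L, ffn_hidden = 16L,
                        epochs = 60L, init_lr = 0.01, seed = 5L)
  m <- train_model(df, cfg = cfg)
  expect_lt(m$history$train_loss[60], 0.05)
  expect_equal(predict(m, df)$.pred, 1, tolerance = 0.05)

  m2 <- train_model(df, cfg = cfg)
  expect_identical(m$history, m2$history)

  expect_error(train_model(df[0, ], cfg = cfg), class = "probekit_data_error")
})

test_that("compiled and reference training engines agree", {
  lib <- generate_library(generator_spec(n = 40, seed = 31))
  cf <- classification_frame(lib)
  cfg <- encoder_config("classification", hidden = 24L, ffn_hidden = 24L,
                        epochs = 3L, init_lr = 1e-3, seed = 2L)
  m_cpp <- train_model(cf[1:30, ], cf[31:40, ], cfg, engine = "cpp")
  m_r <- train_model(cf[1:30, ], cf[31:40, ], cfg, engine = "r")
  expect_equal(m_cpp$history$train_loss, m_r$history$train_loss,
               tolerance = 1e-4)
  expect_equal(predict(m_cpp, cf[31:40, ])$.pred,
               predict(m_r, cf[31:40, ])$.pred, tolerance = 1e-3)
})

test_that("training loss decreases monotonically (smoothed) on noiseless data", {
  lib <- generate_library(generator_spec(n = 150, seed = 8,
                                         noise_sd = default_noise_sd() * 0,
                                         inconsistency_rate = 0))
  cf <- classification_frame(lib)
  cfg <- encoder_config("classification", hidden = 32L, ffn_hidden = 32L,
                        epochs = 12L, init_lr = 2e-3, seed = 6L)
  m <- train_model(cf, cfg = cfg)
  sm <- stats::filter(m$history$train_loss, rep(1 / 3, 3), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-3))
  expect_lt(m$history$train_loss[12], m$history$train_loss[1])
})

test_that("tidy and glance expose training history and summary", {
  df <- tibble::tibble(smiles = c("CCO", "CCC"), label = c(1, 0),
                       abs_query = 370, em_query = 440)
  cfg <- encoder_config("classification", hidden = 8L, ffn_hidden = 8L,
                        epochs = 2L, seed = 1L, batch_size = 2L)
  m <- train_model(df, cfg = cfg)
  td <- tidy(m)
  expect_identical(names(td), c("epoch", "train_loss", "val_metric"))
  expect_equal(nrow(td), 2)
  gl <- glance(m)
  expect_equal(gl$task, "classification")
  expect_equal(gl$n_train, 2)
})
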