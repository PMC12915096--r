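test_that("Murcko scaffolds prune side chains and vanish for acyclic molecules", {
  benzene <- canonicalize_smiles("c1ccccc1")
  expect_identical(murcko_scaffold("Cc1ccccc1"), benzene)
  expect_identical(murcko_scaffold("CCO"), "")
  biphenyl <- canonicalize_smiles("c1ccc(-c2ccccc2)cc1")
  expect_identical(murcko_scaffold("c1ccc(-c2ccccc2)cc1"), biphenyl)
  # linker between rings is retained
  expect_identical(murcko_scaffold("c1ccccc1CCc1ccccc1"),
                   canonicalize_smiles("c1ccccc1CCc1ccccc1"))
  expect_error(murcko_scaffold("C1CC"), class = "probekit_invalid_structure")
})

test_that("fingerprints are deterministic structure identities", {
  fp <- ecfp_fingerprint(c("C1=CC=CC=C1", "c1ccccc1", "CCO"))
  expect_equal(dim(fp), c(3, 2048))
  expect_identical(fp[1, ], fp[2, ])
  expect_gt(sum(fp[1, ]), 0)
  expect_equal(tanimoto(fp[1, ], fp[1, ]), 1)
  expect_lt(tanimoto(fp[1, ], fp[3, ]), 1)
  expect_error(ecfp_fingerprint("CCO", n_bits = 1000),
               class = "probekit_config_error")
})

test_that("scaffold frequency tables rank by count with a dedicated acyclic bin", {
  smi <- c(rep("Cc1ccccc1", 3), rep("CCc1ccccc1", 2))
  tab <- scaffold_frequencies(smi)
  expect_identical(tab$scaffold[1], canonicalize_smiles("c1ccccc1"))
  expect_equal(tab$n[1], 5)

  mixed <- scaffold_frequencies(c("CCO", "CCC", "CC=O"))
  expect_identical(mixed$scaffold, "<acyclic>")
  expect_equal(mixed$n, 3)

  few <- scaffold_frequencies(c("Cc1ccccc1", "CCO"), k = 20)
  expect_equal(nrow(few), 2)
  expect_error(scaffold_frequencies(character(0)),
               class = "probekit_data_error")
})

test_that("chemspace embedding is deterministic, finite, and n x 2", {
  fam <- generate_scaffold_families(10, 42)
  fp <- ecfp_fingerprint(fam$smiles)
  e1 <- suppressWarnings(chemspace_embed(fp, seed = 42))
  e2 <- suppressWarnings(chemspace_embed(fp, seed = 42))
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(20L, 2L))
  expect_true(all(is.finite(e1$tsne1)))
  expect_warning(chemspace_embed(fp, perplexity = 30),
                 "perplexity reduced")
  expect_error(chemspace_embed(fp[1:4, ]), class = "probekit_data_error")
})

train_tiny_models <- function() {
  lib <- generate_library(generator_spec(n = 120, seed = 19))
  cf <- classification_frame(lib)
  l1 <- train_model(
    cf,
    cfg = encoder_config("classification", hidden = 16L, ffn_hidden = 16L,
                         epochs = 3L, init_lr = 1e-3, seed = 4L)
  )
  rf <- regression_frame(lib, "em_wavelength")
  l2 <- train_model(
    rf,
    cfg = encoder_config("regression", target_property = "em_wavelength",
                         hidden = 16L, solvent_hidden = 16L,
                         ffn_hidden = 16L, epochs = 3L, init_lr = 1e-3,
                         seed = 4L)
  )
  list(lib = lib, l1 = l1, l2 = list(em_wavelength = l2))
}

test_that("screening retrieves cached molecules without touching the model", {
  tm <- train_tiny_models()
  cached <- tm$lib$molecules$smiles[1:10]
  libdf <- tibble::tibble(smiles = cached)
  tm$l1$call_counter$n <- 0L
  out <- two_step_screen(libdf, tm$l1, list(),
                         wavelength_pair = c(370, 420), threshold = 1)
  expect_true(all(out$provenance == "retrieved"))
  expect_equal(tm$l1$call_counter$n, 0L)
  # stored experimental labels are returned bit-identically
  expect_setequal(out$activity_score,
                  tm$lib$molecules$label[match(out$smiles,
                                               tm$lib$molecules$smiles)])

  # a different condition is a cache miss
  tm$l1$call_counter$n <- 0L
  out2 <- two_step_screen(libdf[1, ], tm$l1, list(),
                          wavelength_pair = c(500, 600), threshold = 0.5)
  expect_identical(out2$provenance, "predicted")
  expect_equal(tm$l1$call_counter$n, 1L)
})

test_that("survivor count is monotone in the threshold and work is gated on step 1", {
  tm <- train_tiny_models()
  probekit:::pk_with_seed(77, {
    libdf <- tibble::tibble(
      smiles = sample(tm$lib$molecules$smiles, 50)
    )
  })
  counts <- integer(0)
  for (th in c(0, 0.25, 0.5, 0.75, 1)) {
    out <- two_step_screen(libdf, tm$l1, tm$l2,
                           wavelength_pair = c(370, 420),
                           solvent_smiles = "CC#N", threshold = th)
    counts <- c(counts, sum(out$passed_l1))
    # property predictions exist exactly for survivors
    expect_true(all(!is.na(out$em_wavelength[out$passed_l1])))
    expect_true(all(is.na(out$em_wavelength[!out$passed_l1])))
    if (th == 0) expect_true(all(out$passed_l1))
  }
  expect_true(all(diff(counts) <= 0))
})

test_that("step-2 predictor is only called for step-1 survivors", {
  tm <- train_tiny_models()
  libdf <- tibble::tibble(smiles = c("CCCCCCCC", "CCCCCCC"))  # unseen alkanes
  tm$l2$em_wavelength$call_counter$n <- 0L
  out <- two_step_screen(libdf, tm$l1, tm$l2,
                         wavelength_pair = c(370, 420), threshold = 1)
  expect_equal(sum(out$passed_l1), 0)
  expect_equal(tm$l2$em_wavelength$call_counter$n, 0L)
})

test_that("screening output is deterministic and sorted by score then structure", {
  tm <- train_tiny_models()
  libdf <- tibble::tibble(smiles = unique(tm$lib$molecules$smiles)[1:30])
  o1 <- two_step_screen(libdf, tm$l1, tm$l2, c(370, 420), "CC#N", 0.25)
  o2 <- two_step_screen(libdf[sample.int(30), , drop = FALSE], tm$l1, tm$l2,
                        c(370, 420), "CC#N", 0.25)
  expect_equal(o1$smiles, o2$smiles)
  expect_equal(o1$activity_score, o2$activity_score)
  expect_true(all(diff(o1$activity_score) <= 0))
  ties <- split(o1$smiles, o1$activity_score)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))

  # invalid rows are skipped, not fatal
  bad <- dplyr::bind_rows(libdf[1:3, ], tibble::tibble(smiles = "C1CC"))
  ob <- two_step_screen(bad, tm$l1, list(), c(370, 420), threshold = 0.5)
  expect_equal(nrow(ob), 3)
  expect_equal(attr(ob, "n_invalid"), 1L)
  expect_error(two_step_screen(libdf, tm$l1, list(), c(370, 420),
                               threshold = 1.5),
               class = "probekit_domain_error")
})

test_that("chemspace analysis bundles scaffolds, coordinates, and top table", {
  fam <- generate_scaffold_families(8, 7)
  cs <- suppressWarnings(chemspace_analysis(fam, seed = 42, max_iter = 250))
  expect_s3_class(cs, "chemspace_result")
  expect_equal(nrow(cs$coords), 16)
  expect_true(all(c("scaffold", "tsne1", "tsne2", "family") %in%
                    names(cs$coords)))
  expect_equal(dim(cs$fingerprints), c(16, 2048))
  p <- ggplot2::autoplot(cs)
  expect_s3_class(p, "ggplot")
})
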