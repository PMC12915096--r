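test_that("log-log viscosity fit recovers planted parameters exactly on noiseless data", {
  series <- generate_assay_curves("fh", list(C = 1, x = 0.6), noise_sd = 0)
  fit <- fit_forster_hoffmann(series)
  expect_equal(fit$estimates$C, 1, tolerance = 1e-8)
  expect_equal(fit$estimates$x, 0.6, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  flat <- tibble::tibble(x = c(1, 10, 100), intensity = 50)
  expect_equal(fit_forster_hoffmann(flat)$estimates$x, 0)

  expect_error(
    fit_forster_hoffmann(tibble::tibble(x = c(0, 10), intensity = c(1, 2))),
    class = "probekit_domain_error"
  )
  expect_error(
    fit_forster_hoffmann(tibble::tibble(x = c(1, 10), intensity = c(-1, 2))),
    class = "probekit_domain_error"
  )
  expect_error(
    fit_forster_hoffmann(tibble::tibble(x = rep(5, 4), intensity = 1:4)),
    class = "probekit_data_error"
  )
})

test_that("intensity rescaling shifts only the intercept of the viscosity fit", {
  series <- generate_assay_curves("fh", list(C = 0.5, x = 0.55),
                                  noise_sd = 0.5, seed = 3)
  series$intensity <- abs(series$intensity)
  f1 <- fit_forster_hoffmann(series)
  scaled <- dplyr::mutate(series, intensity = intensity * 37)
  f2 <- fit_forster_hoffmann(scaled)
  expect_equal(f2$estimates$x, f1$estimates$x, tolerance = 1e-12)
  expect_equal(f2$estimates$C, f1$estimates$C + log10(37), tolerance = 1e-12)
})

test_that("one-site Kd fit inverts the generating model on the titration grid", {
  series <- generate_assay_curves("kd", list(F0 = 10, Bmax = 100, Kd = 54.8),
                                  noise_sd = 0)
  fit <- fit_saturation_kd(series)
  expect_equal(fit$estimates$Kd, 54.8, tolerance = 54.8 * 0.01)
  expect_equal(fit$estimates$F0, 10, tolerance = 0.1)
  expect_equal(fit$estimates$Bmax, 100, tolerance = 0.5)

  # intensity scale equivariance: doubling I doubles F0 and Bmax only
  doubled <- dplyr::mutate(series, intensity = intensity * 2)
  f2 <- fit_saturation_kd(doubled)
  expect_equal(f2$estimates$Kd, fit$estimates$Kd, tolerance = 1e-6)
  expect_equal(f2$estimates$F0, 2 * fit$estimates$F0, tolerance = 1e-6)
  expect_equal(f2$estimates$Bmax, 2 * fit$estimates$Bmax, tolerance = 1e-6)

  flat <- generate_assay_curves("kd", list(F0 = 20, Bmax = 0, Kd = 50),
                                noise_sd = 0)
  expect_error(fit_saturation_kd(flat), class = "probekit_degenerate_fit")
  expect_error(fit_saturation_kd(series[1:3, ]), class = "probekit_data_error")
})

test_that("Hill fit nests the one-site model and recovers a planted exponent", {
  one_site <- generate_assay_curves("kd", list(F0 = 5, Bmax = 80, Kd = 30),
                                    noise_sd = 0)
  kd_fit <- fit_saturation_kd(one_site)
  hill_fit <- fit_hill(one_site)
  expect_equal(hill_fit$estimates$Kd, kd_fit$estimates$Kd,
               tolerance = 1e-4 * kd_fit$estimates$Kd)
  expect_equal(hill_fit$estimates$h, 1, tolerance = 1e-3)

  coop <- generate_assay_curves("hill",
                                list(F0 = 10, Bmax = 100, Kd = 54.8, h = 2),
                                noise_sd = 0)
  hf <- fit_hill(coop)
  expect_equal(hf$estimates$h, 2, tolerance = 0.02 * 2)
  expect_equal(hf$estimates$Kd, 54.8, tolerance = 0.02 * 54.8)

  expect_error(fit_hill(tibble::tibble(x = numeric(0),
                                       intensity = numeric(0))),
               class = "probekit_data_error")
})

test_that("Kd recovery stays accurate under replicate intensity noise", {
  # quick version of the Monte-Carlo property (full run in acceptance)
  errs <- vapply(1:25, function(b) {
    s <- generate_assay_curves("kd", list(F0 = 10, Bmax = 100, Kd = 54.8),
                               noise_sd = 2, seed = 7000 + b)
    abs(fit_saturation_kd(s)$estimates$Kd - 54.8) / 54.8
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("inhibition rate follows the control-normalized formula", {
  expect_equal(inhibition_rate(200, 50), 75)
  expect_equal(inhibition_rate(100, 100), 0)
  expect_equal(inhibition_rate(100, 0), 100)
  expect_equal(inhibition_rate(100, 150), -50)  # enhancers pass through
  expect_error(inhibition_rate(0, 10), class = "probekit_domain_error")
})

test_that("fit objects expose tidy, glance, bootstrap, and plots", {
  series <- generate_assay_curves("kd", list(F0 = 10, Bmax = 100, Kd = 54.8),
                                  noise_sd = 1, seed = 2)
  fit <- fit_saturation_kd(series)
  td <- tidy(fit)
  expect_setequal(td$term, c("F0", "Bmax", "Kd"))
  gl <- glance(fit)
  expect_equal(gl$model, "saturation_kd")
  expect_lte(gl$r_squared, 1)
  ci <- bootstrap_ci(fit, n_boot = 60, seed = 9)
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(
    ggplot2::autoplot(fit_forster_hoffmann(
      generate_assay_curves("fh", list(C = 1, x = 0.6), noise_sd = 0)
    )),
    "ggplot"
  )
})
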