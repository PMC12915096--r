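pk_new_fit <- function(model, estimates, data, fitted) {
  rss <- sum((data$intensity - fitted)^2)
  tss <- sum((data$intensity - mean(data$intensity))^2)
  structure(
    list(model = model, estimates = estimates, rss = rss,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         data = data, fitted = fitted),
    class = "assay_fit"
  )
}

#' @export
print.assay_fit <- function(x, ...) {
  cat("<assay_fit>", x$model, "\n")
  est <- x$estimates
  cat(" ", paste(names(est), signif(unlist(est), 6), sep = " = ",
                 collapse = ", "), "\n")
  cat("  r_squared =", signif(x$r_squared, 6), " rss =", signif(x$rss, 6), "\n")
  invisible(x)
}

#' Parameter estimates of an assay fit
#' @param x An `assay_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.assay_fit <- function(x, ...) {
  tibble(term = names(x$estimates), estimate = unlist(x$estimates))
}

#' One-row summary of an assay fit
#' @param x An `assay_fit`.
#' @param ... Unused.
#' @export
glance.assay_fit <- function(x, ...) {
  tibble(model = x$model, r_squared = x$r_squared, rss = x$rss,
         n = nrow(x$data))
}

pk_check_series <- function(data, min_distinct = 2) {
  stopifnot(all(c("x", "intensity") %in% names(data)))
  data <- tibble::as_tibble(data)[, c("x", "intensity")]
  if (nrow(data) == 0 || length(unique(data$x)) < min_distinct) {
    abort(paste0("need at least ", min_distinct, " distinct x values"),
          class = "probekit_data_error")
  }
  if (any(data$x < 0)) {
    abort("x values must be non-negative", class = "probekit_domain_error")
  }
  data
}

#' Viscosity sensitivity by the log-log intensity fit
#'
#' Ordinary least squares of `log10(intensity)` on `log10(viscosity)`:
#' `log I = C + x log eta`. The slope `x` is the probe's viscosity
#' sensitivity (a molecular-rotor characteristic); the intercept `C`
#' absorbs instrument scale, so multiplying all intensities by a constant
#' shifts `C` by its log10 and leaves `x` unchanged.
#'
#' @param data Tibble with `x` (viscosity in cP, positive) and `intensity`
#'   (positive, arbitrary units).
#' @return An `assay_fit` with estimates `C`, `x` and the fit `r_squared`.
#' @export
fit_forster_hoffmann <- function(data) {
  data <- pk_check_series(data)
  if (any(data$x <= 0) || any(data$intensity <= 0)) {
    abort("viscosities and intensities must be positive for the log-log fit",
          class = "probekit_domain_error")
  }
  lx <- log10(data$x)
  ly <- log10(data$intensity)
  fit <- stats::lm(ly ~ lx)
  est <- list(C = unname(stats::coef(fit)[1]), x = unname(stats::coef(fit)[2]))
  fitted_log <- stats::fitted(fit)
  out <- pk_new_fit("forster_hoffmann", est, data, 10^fitted_log)
  # r-squared on the fitting (log) scale, as the model is linear there
  tss <- sum((ly - mean(ly))^2)
  out$r_squared <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_
  out$rss <- sum(stats::resid(fit)^2)
  out
}

pk_saturation_starts <- function(data, hill = FALSE) {
  f0 <- min(data$intensity)
  bmax <- max(data$intensity) - min(data$intensity)
  xpos <- data$x[data$x > 0]
  kds <- unique(c(stats::median(xpos), max(xpos) / 10, max(xpos)))
  starts <- lapply(kds, function(kd) list(F0 = f0, Bmax = bmax, Kd = kd))
  if (hill) {
    starts <- unlist(lapply(starts, function(s) {
      lapply(c(1, 2), function(h) c(s, h = h))
    }), recursive = FALSE)
  }
  starts
}

pk_fit_saturation <- function(data, hill) {
  data <- pk_check_series(data, min_distinct = 4)
  if (stats::sd(data$intensity) == 0 ||
      diff(range(data$intensity)) < 1e-12 * max(abs(data$intensity), 1)) {
    abort("flat intensity series: saturation parameters are not identifiable",
          class = "probekit_degenerate_fit")
  }
  formula <- if (hill) {
    intensity ~ F0 + Bmax * x^h / (Kd^h + x^h)
  } else {
    intensity ~ F0 + Bmax * x / (Kd + x)
  }
  best <- NULL
  diagnostics <- character(0)
  for (st in pk_saturation_starts(data, hill)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = st,
        lower = if (hill) c(-Inf, -Inf, 1e-12, 0.05) else c(-Inf, -Inf, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) {
        diagnostics <<- c(diagnostics, conditionMessage(e))
        NULL
      }
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort(paste0("saturation fit failed from all starts: ",
                 paste(unique(diagnostics), collapse = "; ")),
          class = "probekit_fit_failure")
  }
  co <- as.list(stats::coef(best$fit))
  if (abs(co$Bmax) < 1e-9 * max(abs(data$intensity), 1)) {
    abort("fitted Bmax is zero: no specific binding signal",
          class = "probekit_degenerate_fit")
  }
  pk_new_fit(if (hill) "hill" else "saturation_kd", co, data,
             stats::fitted(best$fit))
}

#' One-site saturation binding fit (dissociation constant)
#'
#' Nonlinear least squares of the specific-binding model
#' `I = F0 + Bmax [L] / (Kd + [L])` with multi-start initialization
#' (Kd started at the median, max/10 and max of the positive
#' concentrations). `Kd` is reported in the units of `x`.
#'
#' @param data Tibble with `x` (ligand concentration, e.g. nM) and
#'   `intensity`; at least 4 distinct concentrations.
#' @return An `assay_fit` with estimates `F0`, `Bmax`, `Kd`.
#' @export
fit_saturation_kd <- function(data) pk_fit_saturation(data, hill = FALSE)

#' Hill-model saturation binding fit
#'
#' `I = F0 + Bmax [L]^h / (Kd^h + [L]^h)`; `h = 1` reduces to the one-site
#' model of [fit_saturation_kd()].
#'
#' @inheritParams fit_saturation_kd
#' @return An `assay_fit` with estimates `F0`, `Bmax`, `Kd`, `h`.
#' @export
fit_hill <- function(data) pk_fit_saturation(data, hill = TRUE)

#' Bootstrap confidence intervals for an assay fit
#'
#' Case-resampling bootstrap of the fitted model's parameters.
#'
#' @param fit An `assay_fit` from one of the fitting functions.
#' @param n_boot Number of resamples.
#' @param seed Integer seed.
#' @param level Interval coverage.
#' @return Tibble with `term`, `estimate`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = 1, level = 0.95) {
  refit <- switch(fit$model,
    forster_hoffmann = fit_forster_hoffmann,
    saturation_kd = fit_saturation_kd,
    hill = fit_hill
  )
  draws <- pk_with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      ix <- sample.int(nrow(fit$data), replace = TRUE)
      tryCatch(unlist(refit(fit$data[ix, ])$estimates),
               error = function(e) NULL)
    })
  })
  draws <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  a <- (1 - level) / 2
  tibble(
    term = names(fit$estimates),
    estimate = unlist(fit$estimates),
    lower = apply(draws, 2, stats::quantile, a),
    upper = apply(draws, 2, stats::quantile, 1 - a)
  )
}

#' Drug-screen inhibition rate
#'
#' `(FI_mean_max - FI_drug) / FI_mean_max * 100`, the percentage reduction
#' of reporter fluorescence relative to the uninhibited control. Negative
#' values (enhancers) are passed through, not clipped.
#'
#' @param fi_mean_max Mean maximal (uninhibited) fluorescence intensity;
#'   must be positive.
#' @param fi_drug Fluorescence intensity with the drug candidate.
#' @return Inhibition rate in percent.
#' @examples
#' inhibition_rate(200, 50)  # 75
#' @export
inhibition_rate <- function(fi_mean_max, fi_drug) {
  if (any(fi_mean_max <= 0)) {
    abort("fi_mean_max must be positive", class = "probekit_domain_error")
  }
  (fi_mean_max - fi_drug) / fi_mean_max * 100
}
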