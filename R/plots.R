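#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
#'   geom_col coord_flip theme_minimal scale_x_log10 scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' Training-history curves
#'
#' Training loss and validation metric per epoch.
#'
#' @param object A `dmpnn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmpnn_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_metric"),
                           names_to = "series", values_to = "value")
  ggplot(h, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    labs(x = "epoch", y = NULL,
         title = paste("Training history:", object$cfg$task)) +
    theme_minimal()
}

#' Chemical-space scatter plot
#'
#' t-SNE embedding of the library, colored by a grouping column when one
#' is present (`family`, else scaffold membership of the top scaffold).
#'
#' @param object A `chemspace_result`.
#' @param colour Optional name of a column of `object$coords` to color by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chemspace_result <- function(object, colour = NULL, ...) {
  df <- object$coords
  if (is.null(colour) && "family" %in% names(df)) colour <- "family"
  p <- ggplot(df, aes(x = .data$tsne1, y = .data$tsne2))
  p <- if (!is.null(colour)) {
    p + geom_point(aes(colour = .data[[colour]]), alpha = 0.8)
  } else {
    p + geom_point(alpha = 0.8)
  }
  p + labs(x = "t-SNE 1", y = "t-SNE 2", title = "Chemical space (ECFP4)") +
    theme_minimal()
}

#' Assay fit curve with data
#'
#' Observed intensities and the fitted model curve; log-log axes for the
#' viscosity (Forster-Hoffmann) fit.
#'
#' @param object An `assay_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assay_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble(x = seq(min(df$x), max(df$x), length.out = 200))
  est <- object$estimates
  grid$intensity <- switch(object$model,
    forster_hoffmann = 10^(est$C + est$x * log10(pmax(grid$x, 1e-12))),
    saturation_kd = est$F0 + est$Bmax * grid$x / (est$Kd + grid$x),
    hill = est$F0 + est$Bmax * grid$x^est$h / (est$Kd^est$h + grid$x^est$h)
  )
  p <- ggplot(df, aes(x = .data$x, y = .data$intensity)) +
    geom_point() +
    geom_line(data = grid) +
    labs(title = paste("Assay fit:", object$model)) +
    theme_minimal()
  if (object$model == "forster_hoffmann") {
    p <- p + scale_x_log10() + scale_y_log10() +
      labs(x = "viscosity (cP)", y = "intensity")
  } else {
    p <- p + labs(x = "concentration", y = "intensity")
  }
  p
}

#' Top-scaffold bar chart
#'
#' @param scaffold_freq Tibble from [scaffold_frequencies()].
#' @return A ggplot object.
#' @export
plot_scaffold_frequencies <- function(scaffold_freq) {
  df <- dplyr::mutate(scaffold_freq,
                      scaffold = factor(.data$scaffold,
                                        levels = rev(.data$scaffold)))
  ggplot(df, aes(x = .data$scaffold, y = .data$n)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "count", title = "Most frequent scaffolds") +
    theme_minimal()
}
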