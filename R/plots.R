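#' Plot a mixture model's density
#'
#' Draws the mixture density and, optionally, its weighted components over a
#' gram range.
#'
#' @param object A `mixture_model`.
#' @param window A [trunc_window()] giving the plotting range.
#' @param components If `TRUE`, overlay the weighted component densities.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_model <- function(object, window = trunc_window(),
                                   components = TRUE, ...) {
  grid <- seq(window[["lower"]], window[["upper"]], length.out = 601)
  df <- tibble::tibble(birthweight = grid, density = dmix(object, grid))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$birthweight, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Birthweight (g)", y = "Density (per g)")
  if (components) {
    comp <- purrr::map_dfr(seq_len(n_components(object)), function(j) {
      tibble::tibble(birthweight = grid, component = factor(j),
                     density = object$weight[j] * dnorm(grid, object$mean[j], object$sd[j]))
    })
    p <- p + ggplot2::geom_line(data = comp,
                                ggplot2::aes(colour = .data$component),
                                linetype = "dashed")
  }
  p
}

#' Plot a mixture fit against the data histogram
#'
#' The fitted density superimposed on a density-scaled histogram of the data
#' used for the fit must be supplied, since fits do not retain their data.
#'
#' @param object A `mixture_fit`.
#' @param data The data the model was fitted to (data frame with a
#'   `birthweight` column, or numeric vector).
#' @param binwidth Histogram bin width in grams.
#' @param ... Passed on to [autoplot.mixture_model()].
#' @return A ggplot object.
#' @export
autoplot.mixture_fit <- function(object, data, binwidth = 100, ...) {
  x <- pull_birthweights(data)
  df <- tibble::tibble(birthweight = x)
  autoplot(object$model, ...) +
    ggplot2::geom_histogram(data = df,
                            ggplot2::aes(x = .data$birthweight,
                                         y = ggplot2::after_stat(.data$density)),
                            binwidth = binwidth, alpha = 0.3,
                            inherit.aes = FALSE)
}

#' Overlay competing fitted densities on one histogram
#'
#' Side-by-side comparison of the contaminated normal, the 2-component
#' mixture and a selected-order mixture on a shared histogram of the data.
#'
#' @param data Data frame with a `birthweight` column, or numeric vector.
#' @param fits Named list of fitted models: `mixture_fit`, `mixture_model` or
#'   `contaminated_fit` objects.
#' @param window A [trunc_window()] giving the plotting range.
#' @param binwidth Histogram bin width in grams.
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(data, fits, window = trunc_window(),
                                  binwidth = 100) {
  x <- pull_birthweights(data)
  grid <- seq(window[["lower"]], window[["upper"]], length.out = 1001)
  dens <- purrr::imap_dfr(fits, function(f, name) {
    d <- if (inherits(f, "contaminated_fit")) contaminated_density(f, grid)
    else if (inherits(f, "mixture_fit")) dmix(f$model, grid)
    else dmix(f, grid)
    tibble::tibble(birthweight = grid, density = d, model = name)
  })
  ggplot2::ggplot(tibble::tibble(birthweight = x),
                  ggplot2::aes(x = .data$birthweight)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(.data$density)),
                            binwidth = binwidth, alpha = 0.3) +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density, colour = .data$model),
                       linewidth = 0.7) +
    ggplot2::labs(x = "Birthweight (g)", y = "Density (per g)", colour = NULL)
}
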