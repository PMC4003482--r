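#' Diversity-versus-survivorship overlay
#'
#' Detected-feature counts per sample over age (points), the cubic trend
#' (line), and, when a survivorship table is supplied, the lifespan curve
#' rescaled onto the count axis — the visual linking late-life leveling of
#' metabolite diversity to mortality.
#'
#' @param series A [diversity_series()] tibble.
#' @param lifespan Optional tibble `diet`, `day`, `fraction_alive`.
#' @return A ggplot object, faceted by diet.
#' @export
plot_diversity <- function(series, lifespan = NULL) {
  rng <- range(series$detected_count)
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$age_days,
                                            y = .data$detected_count)) +
    ggplot2::geom_point(shape = 17, colour = "firebrick") +
    ggplot2::geom_smooth(method = "lm",
                         formula = y ~ poly(x, 3, raw = TRUE),
                         se = FALSE, colour = "firebrick") +
    ggplot2::facet_wrap(~diet) +
    ggplot2::labs(x = "age (days)", y = "detected features",
                  title = "Metabolite diversity across lifespan")
  if (!is.null(lifespan)) {
    lifespan <- mutate(lifespan,
                       scaled = rng[1] + .data$fraction_alive * diff(rng))
    p <- p + ggplot2::geom_line(
      data = lifespan,
      ggplot2::aes(x = .data$day, y = .data$scaled), colour = "black"
    )
  }
  p
}

#' Density of matched versus null trajectory correlations
#'
#' @param x A `concordance_test`.
#' @param ... Unused.
#' @return A ggplot object: matched-pair correlation density with the
#'   observed and null medians marked.
#' @method autoplot concordance_test
#' @export
autoplot.concordance_test <- function(x, ...) {
  ggplot2::ggplot(x$correlations, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = x$observed_median_r, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = median(x$null_medians),
                        colour = "grey40", linetype = 2) +
    ggplot2::labs(x = "Pearson r (matched diet pairs)", y = "density",
                  title = sprintf("Cross-diet concordance: median r = %.2f, p = %.3g",
                                  x$observed_median_r, x$p_value))
}

#' P-value histogram of the age-association screen
#'
#' @param x An `age_assoc` object.
#' @param ... Unused.
#' @return A ggplot object with the significance threshold marked.
#' @method autoplot age_assoc
#' @export
autoplot.age_assoc <- function(x, ...) {
  d <- filter(x$results, .data$eligible)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(boundary = 0, bins = 50, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = x$alpha, colour = "firebrick") +
    ggplot2::facet_wrap(~diet) +
    ggplot2::labs(x = "repeated-measures ANOVA p-value", y = "features")
}

#' Sample scores of a PCA projection
#'
#' @param x A `pca_projection`.
#' @param samples Optional sample metadata to colour/shape by (`sample`,
#'   `diet`, `age_days`).
#' @param ... Unused.
#' @return A ggplot object of the first two components.
#' @method autoplot pca_projection
#' @export
autoplot.pca_projection <- function(x, samples = NULL, ...) {
  d <- x$scores
  if (!is.null(samples)) d <- left_join(d, samples, by = "sample")
  aes <- if (!is.null(samples)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$age_days,
                 shape = .data$diet)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2])
    )
}

#' Mean scaled trajectory of each cluster
#'
#' @param cluster_means Output of [cluster_mean_trajectory()].
#' @return A ggplot object, one panel per cluster, one line per diet.
#' @export
plot_cluster_trajectories <- function(cluster_means) {
  ggplot2::ggplot(cluster_means,
                  ggplot2::aes(x = .data$age_days, y = .data$mean_value,
                               colour = .data$diet)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "age (days)", y = "mean scaled level",
                  title = "Cluster mean trajectories")
}

#' Remodeling-delay curves
#'
#' @param x A `delay_curves` object (see [remodeling_delay_curves()]).
#' @param ... Unused.
#' @return A ggplot object: mean scaled up/down trajectories per diet with
#'   quadratic fits.
#' @method autoplot delay_curves
#' @export
autoplot.delay_curves <- function(x, ...) {
  ggplot2::ggplot(x$points,
                  ggplot2::aes(x = .data$age_days, y = .data$mean_scaled,
                               colour = .data$diet,
                               linetype = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm",
                         formula = y ~ poly(x, 2, raw = TRUE), se = FALSE) +
    ggplot2::labs(x = "age (days)", y = "mean scaled level",
                  title = "Remodeling trajectories and dietary delay")
}
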