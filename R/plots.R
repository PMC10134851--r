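#' Boxplots of a weighted profile property by size fraction and domain
#'
#' @param profiles Output of [sample_profiles()].
#' @param metadata Sample metadata with `sample_id` and `fraction`.
#' @param property Property column to plot (default `"gc"`).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, metadata, property = "gc") {
  stopifnot(property %in% names(profiles))
  d <- dplyr::inner_join(profiles, metadata, by = "sample_id") |>
    dplyr::mutate(fraction = factor(.data$fraction,
                                    labels = c("free-living", "particle")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction,
                                  y = .data[[property]],
                                  fill = .data$fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$domain_label), scales = "free_y") +
    ggplot2::labs(x = NULL, y = property) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname ordinate_profiles
#' @param object A `stoich_ordination` object.
#' @param colour_by Optional vector (length = samples) mapped to colour.
#' @export
autoplot.stoich_ordination <- function(object, colour_by = NULL, ...) {
  d <- object$scores
  if (!is.null(colour_by)) d$colour_by <- colour_by
  vf <- object$var_fraction
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(
      x = sprintf("axis 1 (%.1f%%)", 100 * vf[1]),
      y = sprintf("axis 2 (%.1f%%)", 100 * vf[2]),
      caption = sprintf("conditioned on %s", object$conditioned)) +
    ggplot2::theme_bw()
  if (is.null(colour_by)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour_by)) +
    ggplot2::labs(colour = NULL)
}

#' @rdname fit_multitask_lasso
#' @param object An `aa_driver_fit` object.
#' @export
autoplot.aa_driver_fit <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(.data$coefficient != 0)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$residue,
                                                     .data$coefficient),
                                  y = .data$coefficient,
                                  fill = .data$coefficient > 0)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$response), scales = "free_x") +
    ggplot2::labs(x = "amino acid", y = "standardized coefficient") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Effect-size versus significance plot for functional enrichment
#'
#' @param enrichment Output of [ko_enrichment()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$estimate,
                               y = -log10(.data$p_value),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_x") +
    ggplot2::labs(x = "log-ratio model estimate", y = "-log10 p") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
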