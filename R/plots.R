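#' Plot a Boltzmann fit
#'
#' Measured points with the fitted two-state curve.
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot boltzmann_fit
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  d <- as_tibble(object$data)
  vgrid <- tibble(voltage_mV = seq(min(d$voltage_mV), max(d$voltage_mV),
                                   length.out = 200))
  vgrid$g <- predict(object, vgrid)
  ylab <- if (object$kind == "activation") "G / Gmax" else "I / Imax"
  ggplot(d, aes(x = .data$voltage_mV, y = .data$g)) +
    geom_point() +
    geom_line(data = vgrid, colour = "firebrick") +
    labs(
      x = "Membrane voltage (mV)", y = ylab,
      title = sprintf("%s: z = %.2f, V½ = %.1f mV", object$kind,
                      object$z, object$v_half)
    ) +
    theme_minimal()
}

#' Plot a contact map
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot heat map of `C_ij`.
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  keys <- rownames(object$C) %||% as.character(seq_len(nrow(object$C)))
  df <- tidyr::expand_grid(i = keys, j = keys)
  df$C <- as.vector(t(object$C))
  df$i <- factor(df$i, levels = keys)
  df$j <- factor(df$j, levels = keys)
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$C)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Cᵢⱼ",
         title = sprintf("Contact map (c = %.1f Å, σ = %.2f Å)",
                         object$c, object$sigma)) +
    theme_minimal() +
    theme(axis.text = element_blank())
}

#' Betweenness centrality profile plot
#'
#' @param profile Output of [betweenness_profile()].
#' @param highlight Optional character vector of residue keys drawn in
#'   colour (e.g. a planted or published pathway).
#' @return A ggplot of betweenness vs residue number.
#' @export
plot_centrality <- function(profile, highlight = NULL) {
  profile$on_path <- if (is.null(highlight)) FALSE else profile$node %in% highlight
  ggplot(profile, aes(x = .data$resno, y = .data$bc)) +
    geom_segment(aes(xend = .data$resno, yend = 0, colour = .data$on_path),
                 show.legend = !is.null(highlight)) +
    geom_point(aes(colour = .data$on_path), size = 1) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                        labels = c("off path", "highlighted"), name = NULL) +
    facet_wrap(~chain, scales = "free_x") +
    labs(x = "Residue", y = "Betweenness centrality") +
    theme_minimal()
}

#' Metric-vs-energy correlation plot
#'
#' Scatter of a per-construct network metric against the measured
#' gating-energy perturbation, with the least-squares line and the
#' Pearson r annotated.
#'
#' @param df Tibble with the two columns named by `metric` and `energy`,
#'   optionally a `construct` column used for labels.
#' @param metric,energy Column names (strings).
#' @return A ggplot.
#' @export
plot_correlation <- function(df, metric, energy) {
  stats_row <- correlate_metric_vs_energy(df[[metric]], df[[energy]])
  p <- ggplot(df, aes(x = .data[[metric]], y = .data[[energy]])) +
    geom_point() +
    geom_abline(slope = stats_row$slope, intercept = stats_row$intercept,
                colour = "darkgreen") +
    labs(title = sprintf("r = %.3f (n = %d)", stats_row$r, stats_row$n)) +
    theme_minimal()
  if ("construct" %in% names(df)) {
    p <- p + geom_text(aes(label = .data$construct), vjust = -0.7, size = 3)
  }
  p
}
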