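# ggplot2 presentation layer. All plots are views over tidied results;
# nothing quantitative is computed here.

#' @export
#' @method autoplot lifetime_image
autoplot.lifetime_image <- function(object, display_range = c(3.75, 4.75),
                                    ...) {
  df <- tidyr::expand_grid(
    y = seq_len(nrow(object$tau_ns)) - 1,
    x = seq_len(ncol(object$tau_ns)) - 1
  )
  df$tau_ns <- as.vector(t(object$tau_ns))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$tau_ns)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = rev(rainbow(64, start = 0, end = 0.7)),
      limits = display_range, oob = scales_squish, na.value = "black",
      name = "lifetime (ns)"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

# Minimal squish (avoids a hard dependency on the scales package API).
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(range[2], pmax(range[1], x))
}

#' @export
#' @method autoplot phasor_image
autoplot.phasor_image <- function(object, ...) {
  df <- tibble(G = as.vector(object$G), S = as.vector(object$S))
  df <- df[complete.cases(df), , drop = FALSE]
  semi <- tibble(
    G = seq(0, 1, length.out = 200),
    S = sqrt(pmax(0, 0.25 - (seq(0, 1, length.out = 200) - 0.5)^2))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$G, .data$S)) +
    ggplot2::geom_bin2d(bins = 80) +
    ggplot2::geom_path(data = semi, linetype = "dashed", colour = "grey40") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 0.6)) +
    ggplot2::labs(x = "G", y = "S", fill = "pixels")
}

#' @export
#' @method autoplot profile_fit
autoplot.profile_fit <- function(object, points = NULL, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(.data$percent, .data$fit)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80"
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "distance across apical domain (%)",
                  y = "normalised intensity")
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points,
      ggplot2::aes(.data$percent, .data$normalized),
      alpha = 0.25, size = 0.6, inherit.aes = FALSE
    )
  }
  p
}

#' @export
#' @method autoplot division_analysis
autoplot.division_analysis <- function(object, ...) {
  d <- object$daughters
  d <- d[!is.na(d$direction), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sibling_position,
                                  fill = .data$direction)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "proportion of daughters", fill = "movement")
}

#' Bar chart of apical/basal proportions per group
#'
#' @param contingency Output of [direction_contingency()].
#' @param stratum Stratum to show (default `"all"`).
#' @return A ggplot object.
#' @export
plot_direction_proportions <- function(contingency, stratum = "all") {
  sub <- contingency[contingency$stratum == stratum, , drop = FALSE]
  group_col <- setdiff(names(sub), c("stratum", "apical", "basal", "n"))[1]
  long <- tidyr::pivot_longer(sub, c("apical", "basal"),
                              names_to = "direction", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data[[group_col]], .data$count,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "proportion of daughters")
}
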