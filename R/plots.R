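#' @import ggplot2
NULL

#' Boxplots of a response across land-use stages
#'
#' @param values Numeric response per sample.
#' @param sf Sample frame aligned with `values`.
#' @param ylab Axis label.
#' @return A ggplot.
#' @export
plot_stage_boxplot <- function(values, sf, ylab = "value") {
  df <- tibble(value = values, stage = sf$stage, ecosystem = sf$ecosystem)
  ggplot(df, aes(x = .data$stage, y = .data$value, fill = .data$ecosystem)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    geom_jitter(width = 0.15, size = 0.8, alpha = 0.6) +
    scale_fill_manual(values = c(grassland = "#7fbf7b", forest = "#2d6a4f")) +
    labs(x = "land-use stage", y = ylab) +
    theme_minimal()
}

# project (D, Q, R) onto the 2-simplex
simplex_xy <- function(D, Q, R) {
  tibble(x = Q + R / 2, y = R * sqrt(3) / 2, D = D)
}

#' Ternary plot of (D, Q, R) coordinates
#'
#' Projects the dominance / functional-diversity / redundancy triples onto
#' the 2-simplex (D bottom-left, Q bottom-right, R top).
#'
#' @param coords Output of [ternary_coordinates()].
#' @param colour Column to colour by (default `"ecosystem"`).
#' @return A ggplot.
#' @export
plot_ternary <- function(coords, colour = "ecosystem") {
  xy <- simplex_xy(coords$D, coords$Q, coords$R)
  xy$group <- coords[[colour]]
  tri <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot(xy, aes(x = .data$x, y = .data$y)) +
    geom_path(data = tri, linewidth = 0.3, colour = "grey40") +
    geom_point(aes(colour = .data$group), alpha = 0.8) +
    annotate("text", x = c(-0.03, 1.03, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
             label = c("D", "Q", "R"), fontface = "bold") +
    coord_equal() +
    theme_void() +
    labs(colour = colour)
}

#' Forest plot of effect sizes
#'
#' @param es Tibble with `estimate`, `ci_low`, `ci_high` and label columns
#'   (e.g. `stage`, `substrate`).
#' @param label Column to place on the y axis.
#' @return A ggplot.
#' @export
plot_effect_sizes <- function(es, label = "stage") {
  es$lab <- interaction(es[[label]],
                        if ("substrate" %in% names(es)) es$substrate else "",
                        drop = TRUE)
  ggplot(es, aes(x = .data$estimate, y = .data$lab)) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_point() +
    labs(x = "effect size", y = NULL) +
    theme_minimal()
}

#' Mean niche overlap across stages
#'
#' @param summary Overlap summary from [stage_overlap_summary()].
#' @return A ggplot of mean +/- sd per stage, faceted by class.
#' @export
plot_overlap <- function(summary) {
  ggplot(summary, aes(x = .data$stage, y = .data$mean_overlap)) +
    geom_errorbar(aes(ymin = .data$mean_overlap - .data$sd_overlap,
                      ymax = .data$mean_overlap + .data$sd_overlap),
                  width = 0.15) +
    geom_point(size = 2) +
    facet_wrap(~class) +
    labs(x = "land-use stage", y = "mean Levin overlap") +
    theme_minimal()
}

#' @export
autoplot.ms_permanova <- function(object, ...) {
  df <- tibble(component = c("between", "within"),
               sum_sq = c(object$ss_between, object$ss_within))
  ggplot(df, aes(x = .data$component, y = .data$sum_sq)) +
    geom_col(fill = "grey30") +
    labs(y = "sum of squared distances",
         title = sprintf("pseudo-F = %.3g, p = %.3g", object$pseudo_F, object$p)) +
    theme_minimal()
}
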