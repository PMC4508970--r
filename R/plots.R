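#' Stacked ROH genome-coverage barplot
#'
#' One bar per individual, stacked by size-class coverage (G_S, G_M, G_L);
#' bar height is G_R.
#'
#' @param profiles Output of [coverage_profile()].
#' @return A ggplot object.
#' @export
plot_roh_coverage <- function(profiles) {
  long <- profiles |>
    dplyr::select("sample", "g_s", "g_m", "g_l") |>
    tidyr::pivot_longer(-"sample", names_to = "size_class",
                        values_to = "coverage") |>
    dplyr::mutate(size_class = factor(.data$size_class,
                                      levels = c("g_l", "g_m", "g_s"),
                                      labels = c("long", "medium", "short")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$coverage,
                                     fill = .data$size_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genome proportion in ROH",
                  fill = "ROH size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' ROH-sharing track along the genome
#'
#' Step plot of the per-bin count of individuals sharing an ROH, faceted
#' by chromosome.
#'
#' @param track Output of [sharing_track()].
#' @return A ggplot object.
#' @export
plot_sharing_track <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$bin_start / 1e6,
                                      y = .data$sharing)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "individuals sharing ROH") +
    ggplot2::theme_minimal()
}

#' Proportion-in-ROH vs coverage scatter with fitted lines
#'
#' The classic enrichment picture: f (fraction of a class's alt
#' homozygotes inside ROH) against genome ROH coverage, coloured by
#' functional class, with per-class least-squares lines.
#'
#' @param props Output of [roh_proportions()] (one ROH class).
#' @param profiles Output of [coverage_profile()].
#' @param roh_class Which ROH class to display (default "R").
#' @return A ggplot object.
#' @export
plot_enrichment <- function(props, profiles, roh_class = "R") {
  df <- props |>
    dplyr::filter(.data$roh_class == !!roh_class) |>
    dplyr::left_join(profiles[, c("sample", "g_r")], by = "sample")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g_r, y = .data$f,
                                   colour = .data$func_class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "genome ROH coverage (G)",
                  y = "proportion of alt homozygotes in ROH (f)",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' @rdname fit_interaction_model
#' @param object An `roh_interaction` object.
#' @method autoplot roh_interaction
#' @export
autoplot.roh_interaction <- function(object, ...) {
  df <- object$fit$model
  df$group <- factor(df$d, labels = c("D = 0", "D = 1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$f,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "coverage G", y = "response f", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
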