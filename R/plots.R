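#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a response-surface map
#'
#' Filled raster of predicted NCV over the coded-level plane of the pair,
#' with contour lines; lower NCV (stronger killing) is darker.
#'
#' @param object An `rsm_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rsm_grid
#' @export
autoplot.rsm_grid <- function(object, ...) {
  pair <- attr(object, "pair")
  ggplot2::ggplot(object, ggplot2::aes(.data$level_a, .data$level_b,
                                       fill = .data$ncv, z = .data$ncv)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "Predicted NCV") +
    ggplot2::labs(x = paste(pair[1], "(coded level)"),
                  y = paste(pair[2], "(coded level)"),
                  title = paste("Response surface:", pair[1], "+", pair[2])) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object (1 - specificity vs sensitivity with the chance
#'   diagonal and the AUC in the subtitle).
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- dplyr::arrange(object$points, 1 - .data$specificity,
                        .data$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(1 - .data$specificity,
                                    .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = "Screen-outcome concordance ROC",
      subtitle = sprintf("AUC %.3f (95%% CI %.3f-%.3f), cutoff NCV %.4f",
                         object$auc, object$auc_ci[1], object$auc_ci[2],
                         object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot a combination-index curve
#'
#' CI against affected fraction with the additivity line CI = 1.
#'
#' @param object A `ci_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ci_curve
#' @export
autoplot.ci_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fa, .data$ci)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(F[a] ~ "(fraction affected)"),
                  y = "Combination index",
                  title = "Chou-Talalay combination index") +
    ggplot2::theme_minimal()
}

#' Plot a Bliss excess matrix
#'
#' Tile map of excess over Bliss independence (percentage points); red =
#' synergistic excess, blue = antagonistic deficit.
#'
#' @param object A `bliss_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bliss_result
#' @export
autoplot.bliss_result <- function(object, ...) {
  df <- tidy.bliss_result(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$dose_a),
                                   factor(.data$dose_b),
                                   fill = .data$excess)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  name = "Excess (pp)") +
    ggplot2::labs(x = "Drug A dose (uM)", y = "Drug B dose (uM)",
                  title = sprintf("Bliss excess: score %.1f (%s)",
                                  object$score, object$classification)) +
    ggplot2::theme_minimal()
}

#' Plot a combination ranking
#'
#' Top therapies by mean NCV with +/- SD error bars (smaller = stronger
#' predicted killing).
#'
#' @param object A `qpop_ranking`.
#' @param top_k Number of therapies shown (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qpop_ranking
#' @export
autoplot.qpop_ranking <- function(object, top_k = 10L, ...) {
  top <- utils::head(tibble::as_tibble(object), top_k)
  top$therapy <- factor(top$therapy, levels = rev(top$therapy))
  ggplot2::ggplot(top, ggplot2::aes(.data$mean_ncv, .data$therapy)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$mean_ncv - .data$sd_ncv,
                                          xmax = .data$mean_ncv + .data$sd_ncv)) +
    ggplot2::labs(x = "Mean NCV over dose permutations (+/- SD)", y = NULL,
                  title = sprintf("Top %d ranked therapies", nrow(top))) +
    ggplot2::theme_minimal()
}
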