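# broom-style tidiers and ggplot2 autoplot methods for fitted objects

#' @method tidy structural_connectome
#' @export
tidy.structural_connectome <- function(x, ...) {
  e <- upper_edges(x$n_rois)
  idx <- cbind(e$roi_i, e$roi_j)
  dplyr::filter(
    dplyr::mutate(e, weight = x$weights[idx], support = x$support[idx] > 0),
    .data$support)
}

#' @method tidy agl_fit
#' @export
tidy.agl_fit <- function(x, ...) {
  e <- upper_edges(nrow(x$precision))
  idx <- cbind(e$roi_i, e$roi_j)
  dplyr::mutate(e, precision = x$precision[idx],
                in_support = x$support_graph[idx])
}

#' @method glance agl_fit
#' @export
glance.agl_fit <- function(x, ...) {
  tibble::tibble(
    n_rois = nrow(x$precision),
    n_edges = sum(x$support_graph[upper.tri(x$support_graph)]),
    lambda_sc = x$lambda_sc, lambda_non_sc = x$lambda_non_sc,
    duality_gap = x$gap, iterations = x$iterations)
}

#' @method tidy fc_fit
#' @export
tidy.fc_fit <- function(x, ...) {
  e <- upper_edges(nrow(x$precision))
  idx <- cbind(e$roi_i, e$roi_j)
  dplyr::mutate(e,
                correlation = x$correlation[idx],
                partial_correlation = x$partial_correlation[idx],
                precision = x$precision[idx],
                in_support = x$support_graph[idx])
}

#' @method glance fc_fit
#' @export
glance.fc_fit <- function(x, ...) {
  tibble::tibble(
    n_rois = nrow(x$precision),
    n_timepoints = x$n_timepoints,
    n_edges = sum(x$support_graph[upper.tri(x$support_graph)]),
    lambda_sc = x$agl$lambda_sc, lambda_non_sc = x$agl$lambda_non_sc,
    ridge_delta = x$ridge_delta)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$curve

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    selected_lambda_sc = x$selected_lambda_sc,
    selected_lambda_gl = x$selected_lambda_gl,
    lambda_non_sc = x$lambda_non_sc,
    n_subjects = x$n_subjects)
}

#' Deviance curves of the adaptive vs plain graphical lasso
#'
#' Mean split-half cross-validated deviance per penalty value, one curve per
#' method, with +/- 1 sd ribbons across subjects; the selected SC penalty is
#' marked.
#'
#' @param object A `cv_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$lambda, y = .data$mean_deviance,
                               colour = .data$method,
                               fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_deviance - .data$sd_deviance,
      ymax = .data$mean_deviance + .data$sd_deviance),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_lambda_sc,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "penalty", y = "cross-validated deviance",
                  colour = "method", fill = "method")
}

#' Heatmap of a structural connectome
#'
#' @param object A `structural_connectome`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot structural_connectome
#' @export
autoplot.structural_connectome <- function(object, ...) {
  p <- object$n_rois
  df <- tidyr::crossing(roi_i = seq_len(p), roi_j = seq_len(p))
  df$weight <- object$weights[cbind(df$roi_i, df$roi_j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$roi_i, .data$roi_j,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "ROI", y = "ROI",
                  fill = paste0("W (", object$mode, ")"))
}

#' @method tidy comm_fit
#' @export
tidy.comm_fit <- function(x, ...) x$coefficients

#' @method glance comm_fit
#' @export
glance.comm_fit <- function(x, ...) {
  tibble::tibble(n_edges = x$n_edges, n_modulated = x$n_modulated,
                 separation = x$separation,
                 deviance = if (is.null(x$model)) NA_real_
                            else x$model$deviance,
                 aic = if (is.null(x$model)) NA_real_ else x$model$aic)
}

#' Flagged-edge fractions from edge-wise damage GLMs
#'
#' Bar chart of the fraction of FDR-flagged edges per stratum, as produced
#' by [modulation_summary()] (optionally with a `level` column when several
#' response levels are combined).
#'
#' @param object A tibble from [modulation_summary()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_modulation_summary <- function(object, ...) {
  mapping <- if ("level" %in% names(object)) {
    ggplot2::aes(.data$stratum, .data$fraction, fill = .data$level)
  } else {
    ggplot2::aes(.data$stratum, .data$fraction)
  }
  ggplot2::ggplot(object, mapping) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of edges modulated")
}
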