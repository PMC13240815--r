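#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Top-view plot of a point cloud
#'
#' XY projection colored by instance (when present), semantic label, or
#' height.
#'
#' @param object A [point_cloud()].
#' @param color One of `"instance"`, `"semantic"`, `"z"`; defaults to the
#'   most informative column present.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot point_cloud
#' @export
autoplot.point_cloud <- function(object, color = NULL, ...) {
  color <- color %||% if (!is.null(object[["instance"]])) "instance"
    else if (!is.null(object[["semantic"]])) "semantic" else "z"
  df <- tibble::as_tibble(object)
  if (color %in% c("instance", "semantic")) df[[color]] <- factor(df[[color]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data[[color]])) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = color) +
    ggplot2::theme_minimal()
}

#' Precision-recall curve of a segmentation evaluation
#'
#' @param object A `segmentation_eval` from [evaluate_segmentation()].
#' @param ... Unused.
#' @return A ggplot of the stepwise precision-recall curve, annotated
#'   with the AP.
#' @method autoplot segmentation_eval
#' @export
autoplot.segmentation_eval <- function(object, ...) {
  ggplot2::ggplot(object$pr_curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("AP = %.3f at IoU >= %.2f", object$ap, object$tau),
                  x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' Search trajectory of an adaptive-clustering fit
#'
#' @param object An `aloc_fit` from [optimize_clustering()].
#' @param ... Unused.
#' @return A ggplot of candidate and incumbent feedback scores per
#'   iteration.
#' @method autoplot aloc_fit
#' @export
autoplot.aloc_fit <- function(object, ...) {
  tr <- object$trajectory
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$candidate_score,
                                     colour = .data$phase), size = 1) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_score)) +
    ggplot2::labs(y = "feedback score", x = "iteration") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-reference scatter of structural parameters
#'
#' @param object An `agreement_report` from [agreement()].
#' @param ... Unused.
#' @return A ggplot faceted by parameter with the identity line.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  long <- purrr::map_dfr(object$params, function(p) {
    tibble::tibble(parameter = p,
                   predicted = object$data[[paste0(p, "_pred")]],
                   reference = object$data[[paste0(p, "_true")]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$reference, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "reference", y = "predicted") +
    ggplot2::theme_minimal()
}
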