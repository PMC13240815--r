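#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a segmentation result into a per-point tibble
#'
#' @param x A `segmentation_result` from [segment()].
#' @param ... Unused.
#' @return A tibble with coordinates, semantic probability and predicted
#'   labels, one row per point.
#' @method tidy segmentation_result
#' @export
tidy.segmentation_result <- function(x, ...) {
  tibble::as_tibble(x$points)
}

#' One-row summary of a segmentation result
#'
#' @inheritParams tidy.segmentation_result
#' @return A tibble: point count, predicted crown fraction, instance
#'   count, mean foreground probability, mode.
#' @method glance segmentation_result
#' @export
glance.segmentation_result <- function(x, ...) {
  p <- x$points
  tibble::tibble(
    n_points = nrow(p),
    crown_fraction = mean(p$pred_semantic == 1L),
    n_instances = length(unique(p$pred_instance[p$pred_instance > 0L])),
    mean_prob = mean(p$prob),
    mode = x$provenance$mode
  )
}

#' Tidy matched instance pairs
#'
#' @param x An `instance_match` from [match_instances()].
#' @param ... Unused.
#' @return Tibble of matched (pred, gt) pairs with IoU.
#' @method tidy instance_match
#' @export
tidy.instance_match <- function(x, ...) x$pairs

#' One-row instance-matching summary
#'
#' @inheritParams tidy.instance_match
#' @return Tibble with tp, fp, fn, precision, recall, fscore, tau.
#' @method glance instance_match
#' @export
glance.instance_match <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, precision = x$precision,
                 recall = x$recall, fscore = x$fscore, tau = x$tau)
}

#' Tidy a full segmentation evaluation
#'
#' @param x A `segmentation_eval` from [evaluate_segmentation()].
#' @param ... Unused.
#' @return The precision-recall curve tibble.
#' @method tidy segmentation_eval
#' @export
tidy.segmentation_eval <- function(x, ...) x$pr_curve

#' One-row segmentation evaluation summary
#'
#' @inheritParams tidy.segmentation_eval
#' @return Tibble with miou, precision, recall, fscore, ap, tau.
#' @method glance segmentation_eval
#' @export
glance.segmentation_eval <- function(x, ...) {
  tibble::tibble(miou = x$miou, precision = x$match$precision,
                 recall = x$match$recall, fscore = x$match$fscore,
                 ap = x$ap, tau = x$tau)
}

#' Tidy an adaptive-clustering fit
#'
#' @param x An `aloc_fit` from [optimize_clustering()].
#' @param ... Unused.
#' @return The per-iteration search trajectory tibble.
#' @method tidy aloc_fit
#' @export
tidy.aloc_fit <- function(x, ...) x$trajectory

#' One-row adaptive-clustering summary
#'
#' @inheritParams tidy.aloc_fit
#' @return Tibble with backend, best score, instance count and the best
#'   parameter pair.
#' @method glance aloc_fit
#' @export
glance.aloc_fit <- function(x, ...) {
  tibble::tibble(backend = x$backend, best_score = x$best_score,
                 n_instances = length(unique(x[["instance"]][x[["instance"]] > 0L])),
                 theta1 = x$theta_best[1] %||% NA_real_,
                 theta2 = x$theta_best[2] %||% NA_real_)
}

#' Tidy a structural-parameter agreement report
#'
#' @param x An `agreement_report` from [agreement()].
#' @param ... Unused.
#' @return Tibble with parameter, block, n, r_squared, rmse.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) x$table

#' One-row agreement summary (pooled blocks)
#'
#' @inheritParams tidy.agreement_report
#' @return Wide tibble of pooled R-squared and RMSE per parameter.
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  pooled <- x$table[x$table$block == "all", ]
  tidyr::pivot_wider(pooled[, c("parameter", "r_squared", "rmse")],
                     names_from = "parameter",
                     values_from = c("r_squared", "rmse"))
}
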