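#' Semantic mean intersection-over-union
#'
#' Mean over classes of `TP / (TP + FP + FN)` for the two semantic classes
#' (0 = background, 1 = crown). A class absent from both prediction and
#' ground truth is excluded from the mean with a warning.
#'
#' @param pred,gt Equal-length label vectors in \{0, 1\}.
#' @return Scalar mIoU in [0, 1].
#' @export
semantic_miou <- function(pred, gt) {
  stopifnot(length(pred) == length(gt),
            all(pred %in% c(0, 1)), all(gt %in% c(0, 1)))
  ious <- c()
  for (cls in c(0, 1)) {
    tp <- sum(pred == cls & gt == cls)
    fp <- sum(pred == cls & gt != cls)
    fn <- sum(pred != cls & gt == cls)
    if (tp + fp + fn == 0) {
      warning(sprintf("class %d absent from both pred and gt; excluded from mIoU", cls))
      next
    }
    ious <- c(ious, tp / (tp + fp + fn))
  }
  mean(ious)
}

#' Match predicted tree instances to ground truth at an IoU threshold
#'
#' Point-set IoU is computed for every overlapping (pred, gt) instance
#' pair; pairs are matched one-to-one greedily in descending IoU (ties by
#' lower pred then gt id) and kept when `IoU >= tau`. Unmatched predictions
#' count as false positives, unmatched ground-truth instances as false
#' negatives, so `TP + FN = #gt` and `TP + FP = #pred`. Label 0 is
#' background on both sides and never matched.
#'
#' @param pred,gt Instance label vectors over the same points (0 =
#'   background).
#' @param tau IoU threshold in (0, 1]; 0.5 by default (the conventional
#'   instance-matching operating point).
#' @return An `instance_match` object: `pairs` (tibble of matched pred/gt
#'   ids with IoU), `tp`, `fp`, `fn`, `precision`, `recall`, `fscore`,
#'   `tau`.
#' @export
match_instances <- function(pred, gt, tau = 0.5) {
  stopifnot(length(pred) == length(gt))
  pred_ids <- sort(unique(pred[pred > 0]))
  gt_ids <- sort(unique(gt[gt > 0]))
  cand <- instance_iou_pairs(pred, gt)
  cand <- cand[cand$iou >= tau, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$pred_id, cand$gt_id), , drop = FALSE]
  used_p <- used_g <- c()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$pred_id[i] %in% used_p) && !(cand$gt_id[i] %in% used_g)) {
      keep[i] <- TRUE
      used_p <- c(used_p, cand$pred_id[i])
      used_g <- c(used_g, cand$gt_id[i])
    }
  }
  pairs <- tibble::as_tibble(cand[keep, , drop = FALSE])
  tp <- nrow(pairs)
  fp <- length(pred_ids) - tp
  fn <- length(gt_ids) - tp
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  structure(list(pairs = pairs, tp = tp, fp = fp, fn = fn,
                 precision = pre, recall = rec,
                 fscore = f_score(pre, rec), tau = tau),
            class = "instance_match")
}

# IoU for every overlapping (pred, gt) instance pair via a cross-tab
instance_iou_pairs <- function(pred, gt) {
  fg <- pred > 0 | gt > 0
  p <- pred[fg]; g <- gt[fg]
  tab <- table(pred_id = p, gt_id = g)
  psize <- tapply(rep(1, length(p)), p, sum)
  gsize <- tapply(rep(1, length(g)), g, sum)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$pred_id <- as.numeric(df$pred_id)
  df$gt_id <- as.numeric(df$gt_id)
  df <- df[df$pred_id > 0 & df$gt_id > 0 & df$Freq > 0, , drop = FALSE]
  inter <- df$Freq
  uni <- psize[as.character(df$pred_id)] + gsize[as.character(df$gt_id)] - inter
  data.frame(pred_id = df$pred_id, gt_id = df$gt_id,
             intersection = inter, union = as.numeric(uni),
             iou = inter / as.numeric(uni))
}

#' @export
print.instance_match <- function(x, ...) {
  cat(sprintf("# Instance matching at IoU >= %.2f: TP %d, FP %d, FN %d | P %.3f R %.3f F %.3f\n",
              x$tau, x$tp, x$fp, x$fn, x$precision, x$recall, x$fscore))
  invisible(x)
}

#' Harmonic mean of precision and recall
#'
#' `F = 2 P R / (P + R)`, defined as 0 when both are 0.
#'
#' @param pre,rec Values in [0, 1].
#' @return Scalar F-score.
#' @export
f_score <- function(pre, rec) {
  stopifnot(pre >= 0, pre <= 1, rec >= 0, rec <= 1)
  if (pre + rec == 0) return(0)
  2 * pre * rec / (pre + rec)
}

#' Average precision of scored instance predictions
#'
#' Predictions are ranked by descending confidence; each is matched (in
#' rank order) to the unmatched ground-truth instance of highest IoU,
#' counting as a true positive when `IoU >= tau`. AP is the area under the
#' resulting stepwise precision-recall curve by all-point integration:
#' `AP = sum_k (R_k - R_{k-1}) * P_k`.
#'
#' @param pred Instance label vector (0 = background).
#' @param scores Named or ordered numeric confidences, one per predicted
#'   instance id (in ascending id order when unnamed).
#' @param gt Ground-truth instance vector.
#' @param tau IoU threshold.
#' @return List with `ap` and `pr_curve` (tibble: rank, precision, recall).
#' @export
average_precision <- function(pred, scores, gt, tau = 0.5) {
  pred_ids <- sort(unique(pred[pred > 0]))
  n_gt <- length(unique(gt[gt > 0]))
  if (length(pred_ids) == 0) {
    return(list(ap = 0, pr_curve = tibble::tibble(rank = integer(),
                                                  precision = double(),
                                                  recall = double())))
  }
  if (!is.null(names(scores))) scores <- scores[as.character(pred_ids)]
  stopifnot(length(scores) == length(pred_ids))
  ord <- order(-scores, pred_ids)
  cand <- instance_iou_pairs(pred, gt)
  matched_gt <- c()
  is_tp <- logical(length(ord))
  for (r in seq_along(ord)) {
    pid <- pred_ids[ord[r]]
    rows <- cand[cand$pred_id == pid & !(cand$gt_id %in% matched_gt) &
                   cand$iou >= tau, , drop = FALSE]
    if (nrow(rows)) {
      best <- rows[order(-rows$iou, rows$gt_id)[1], ]
      matched_gt <- c(matched_gt, best$gt_id)
      is_tp[r] <- TRUE
    }
  }
  tp_cum <- cumsum(is_tp)
  prec <- tp_cum / seq_along(ord)
  rec <- if (n_gt == 0) rep(0, length(ord)) else tp_cum / n_gt
  ap <- sum(diff(c(0, rec)) * prec)
  list(ap = ap,
       pr_curve = tibble::tibble(rank = seq_along(ord), precision = prec,
                                 recall = rec))
}

#' Instance confidence scores from semantic probabilities
#'
#' The confidence of a predicted instance is the mean foreground
#' probability of its points -- the convention used for ranking instances
#' in the average-precision computation.
#'
#' @param instance Instance label vector.
#' @param prob Per-point foreground probabilities.
#' @return Named numeric vector of per-instance confidences.
#' @export
instance_confidence <- function(instance, prob) {
  stopifnot(length(instance) == length(prob))
  idx <- instance > 0
  vapply(split(prob[idx], instance[idx]), mean, 0)
}

#' Full segmentation evaluation report
#'
#' Combines semantic mIoU, instance matching at `tau`, and average
#' precision into one tidy row; the per-instance detail is available via
#' `tidy()` on the returned object.
#'
#' @param pred_semantic,gt_semantic Semantic label vectors.
#' @param pred_instance,gt_instance Instance label vectors.
#' @param prob Optional per-point foreground probabilities for AP ranking;
#'   defaults to instance size ranking.
#' @param tau IoU threshold.
#' @return A `segmentation_eval` object.
#' @export
evaluate_segmentation <- function(pred_semantic, gt_semantic,
                                  pred_instance, gt_instance,
                                  prob = NULL, tau = 0.5) {
  miou <- semantic_miou(pred_semantic, gt_semantic)
  m <- match_instances(pred_instance, gt_instance, tau = tau)
  conf <- if (is.null(prob)) {
    sz <- table(pred_instance[pred_instance > 0])
    stats::setNames(as.numeric(sz) / max(1, max(sz)), names(sz))
  } else instance_confidence(pred_instance, prob)
  ap <- average_precision(pred_instance, conf, gt_instance, tau = tau)
  structure(list(miou = miou, match = m, ap = ap$ap, pr_curve = ap$pr_curve,
                 tau = tau),
            class = "segmentation_eval")
}

#' @export
print.segmentation_eval <- function(x, ...) {
  cat(sprintf("# Segmentation evaluation (IoU tau = %.2f)\n", x$tau))
  cat(sprintf("  mIoU %.4f | P %.4f R %.4f F %.4f AP %.4f\n",
              x$miou, x$match$precision, x$match$recall, x$match$fscore, x$ap))
  invisible(x)
}
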