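test_that("semantic mIoU handles identity, complement, and mixed cases", {
  gt <- c(0, 0, 1, 1, 1, 0)
  expect_equal(semantic_miou(gt, gt), 1)
  expect_equal(semantic_miou(1 - gt, gt), 0)
  # engineered per-class IoUs 0.5 and 1.0 average to 0.75:
  # class 1 perfect, class 0 half-covered
  pred <- c(0, 0, 0, 0, 1, 1)
  gt2 <- c(0, 0, 0, 1, 1, 1)
  # class 0: TP 3, FP 1, FN 0 -> 0.75 ; class 1: TP 2, FP 0, FN 1 -> 2/3
  expect_equal(semantic_miou(pred, gt2), mean(c(3 / 4, 2 / 3)))
  expect_warning(semantic_miou(c(1, 1), c(1, 1)), "absent")
})

test_that("instance matching satisfies the conservation identities", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(30:80, 1)
    pred <- fixture_random_partition(n, sample(2:6, 1))
    gt <- fixture_random_partition(n, sample(2:6, 1))
    m <- match_instances(pred, gt, tau = 0.5)
    expect_equal(m$tp + m$fn, length(unique(gt[gt > 0])))
    expect_equal(m$tp + m$fp, length(unique(pred[pred > 0])))
    expect_true(all(m$pairs$iou >= 0.5))
    expect_false(any(duplicated(m$pairs$pred_id)))
    expect_false(any(duplicated(m$pairs$gt_id)))
  }
})

test_that("identical maps give perfect matching; split halves sit on the IoU boundary", {
  gt <- rep(1:3, each = 20)
  m <- match_instances(gt, gt)
  expect_equal(m$tp, 3); expect_equal(m$fp, 0); expect_equal(m$fn, 0)
  expect_equal(m$fscore, 1)

  # one gt tree split into two equal predicted halves: each half has
  # IoU exactly 0.5 which counts as a match under the >= rule
  gt1 <- rep(1L, 40)
  pred <- rep(c(1L, 2L), each = 20)
  m2 <- match_instances(pred, gt1, tau = 0.5)
  expect_equal(m2$tp, 1)   # one half matches, the other is a false positive
  expect_equal(m2$fp, 1)
  # just above the boundary nothing matches
  m3 <- match_instances(pred, gt1, tau = 0.500001)
  expect_equal(m3$tp, 0)
})

test_that("precision, recall and F follow the counting identities", {
  # TP 3, FP 1, FN 2
  pred <- c(rep(1, 10), rep(2, 10), rep(3, 10), rep(4, 10), rep(0, 20))
  gt <- c(rep(1, 10), rep(2, 10), rep(3, 10), rep(0, 10), rep(4, 10), rep(5, 10))
  m <- match_instances(pred, gt, tau = 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(3, 1, 2))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$fscore, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(round(m$fscore, 4), 0.6667)

  expect_equal(f_score(0.7, 0.7), 0.7)
  expect_equal(f_score(1, 0), 0)
  expect_equal(f_score(0, 0), 0)
  expect_equal(f_score(0.75, 0.6), 0.666667, tolerance = 1e-6)
})

test_that("greedy matching agrees with the exhaustive optimal assignment (<= 6 instances)", {
  set.seed(52)
  for (rep in 1:40) {
    n <- sample(24:60, 1)
    pred <- fixture_random_partition(n, sample(2:6, 1))
    gt <- fixture_random_partition(n, sample(2:6, 1))
    tau <- sample(c(0.3, 0.5), 1)
    m <- match_instances(pred, gt, tau = tau)
    expect_equal(m$tp, oracle_optimal_match(pred, gt, tau))
  }
})

test_that("metrics are invariant to instance label permutations", {
  set.seed(53)
  n <- 60
  pred <- fixture_random_partition(n, 4)
  gt <- fixture_random_partition(n, 5)
  m1 <- match_instances(pred, gt)
  relab <- sample(10:20, 4)
  pred2 <- relab[pred]
  m2 <- match_instances(pred2, gt)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(m2$tp, m2$fp, m2$fn))
  expect_equal(m1$fscore, m2$fscore)
  expect_equal(semantic_miou(as.integer(pred > 2), as.integer(gt > 2)),
               semantic_miou(as.integer(pred > 2), as.integer(gt > 2)))
})

test_that("average precision hits the degenerate and boundary cases", {
  gt <- rep(1:2, each = 10)
  # all predictions correct
  ap1 <- average_precision(gt, c(`1` = 0.9, `2` = 0.8), gt, tau = 0.5)
  expect_equal(ap1$ap, 1)
  # all predictions wrong (no overlap above tau)
  pred_bad <- c(rep(1L, 3), rep(0L, 14), rep(2L, 3))
  ap0 <- average_precision(pred_bad, c(`1` = 0.9, `2` = 0.8), gt, tau = 0.5)
  expect_equal(ap0$ap, 0)
  # no predictions at all
  expect_equal(average_precision(rep(0L, 20), numeric(0), gt)$ap, 0)
})

test_that("average precision equals the rectangle-sum oracle", {
  # 3 predictions in confidence order: correct, wrong, correct, over 2 gt
  gt <- c(rep(1L, 10), rep(2L, 10), rep(0L, 6))
  pred <- c(rep(1L, 10), rep(2L, 10), rep(3L, 6))
  # instance 3 overlaps only background; 1 and 2 are exact
  scores <- c(`1` = 0.9, `3` = 0.8, `2` = 0.7)
  res <- average_precision(pred, scores, gt, tau = 0.5)
  expect_equal(res$ap, oracle_ap_rect(c(TRUE, FALSE, TRUE), 2), tolerance = 1e-9)
  expect_equal(res$ap, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-9)

  set.seed(54)
  for (rep in 1:20) {
    n <- sample(40:80, 1)
    predr <- fixture_random_partition(n, sample(2:5, 1))
    gtr <- fixture_random_partition(n, sample(2:5, 1))
    ids <- sort(unique(predr))
    sc <- stats::setNames(runif(length(ids)), ids)
    res <- average_precision(predr, sc, gtr, tau = 0.4)
    # re-derive the TP flags independently in confidence order
    ord <- ids[order(-sc, ids)]
    matched <- c(); flags <- logical(length(ord))
    for (r in seq_along(ord)) {
      cands <- setdiff(unique(gtr), matched)
      ious <- vapply(cands, function(g) oracle_iou(which(predr == ord[r]),
                                                   which(gtr == g)), 0)
      if (length(ious) && max(ious) >= 0.4) {
        matched <- c(matched, cands[which.max(ious)])
        flags[r] <- TRUE
      }
    }
    expect_equal(res$ap, oracle_ap_rect(flags, length(unique(gtr))),
                 tolerance = 1e-9)
  }
})

test_that("all reported metrics live in [0,1] with the F bounds identities", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(30:70, 1)
    pred <- fixture_random_partition(n, sample(2:5, 1))
    gt <- fixture_random_partition(n, sample(2:5, 1))
    ev <- evaluate_segmentation(as.integer(pred > 1), as.integer(gt > 1),
                                pred, gt)
    g <- glance(ev)
    vals <- c(g$miou, g$precision, g$recall, g$fscore, g$ap)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_lte(g$fscore, max(g$precision, g$recall) + 1e-12)
    if (g$precision + g$recall > 0) {
      lo <- min(g$precision, g$recall); hi <- max(g$precision, g$recall)
      expect_gte(g$fscore + 1e-12, lo * 2 * hi / (lo + hi))
    }
  }
})

test_that("instance confidences are mean foreground probabilities", {
  inst <- c(1L, 1L, 2L, 0L)
  prob <- c(0.9, 0.7, 0.6, 0.1)
  conf <- instance_confidence(inst, prob)
  expect_equal(unname(conf), c(0.8, 0.6))
})
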