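# Metrics: IoU, matching, PR, AP, mAP aggregation, F1, confusion matrix.

test_that("IoU handles identity, disjoint and the analytic overlap case", {
  expect_equal(iou_xyxy(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(iou_xyxy(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0.0)
  expect_equal(iou_xyxy(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_equal(iou_xyxy(c(1, 0, 3, 2), c(0, 0, 2, 2)), 1 / 3)  # symmetric
  expect_error(iou_xyxy(c(1, 1, 1, 2), c(0, 0, 2, 2)), "degenerate")
})

test_that("matching is greedy one-to-one by confidence", {
  gt <- data.frame(class_id = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  d1 <- data.frame(class_id = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10,
                   confidence = 0.9)
  m <- match_detections(d1, gt, 0.5)
  expect_equal(c(m$n_tp, m$n_fp, m$n_fn), c(1, 0, 0))
  # two detections on one ground truth: one TP, one FP
  d2 <- rbind(d1, transform(d1, confidence = 0.8))
  m2 <- match_detections(d2, gt, 0.5)
  expect_equal(c(m2$n_tp, m2$n_fp, m2$n_fn), c(1, 1, 0))
  expect_equal(m2$tp, c(TRUE, FALSE))
  # class-strict: right box, wrong class
  d3 <- transform(d1, class_id = 1L)
  m3 <- match_detections(d3, gt, 0.5)
  expect_equal(c(m3$n_tp, m3$n_fp, m3$n_fn), c(0, 1, 1))
})

test_that("matching and AP agree with brute-force oracles on random scenes", {
  set.seed(31)
  ok <- TRUE
  for (trial in 1:200) {
    sc <- random_scene()
    if (!nrow(sc$dets)) next
    m <- match_detections(sc$dets, sc$gts, 0.5)
    ok <- ok && identical(m$tp, oracle_match(sc$dets, sc$gts, 0.5))
    n_gt <- nrow(sc$gts)
    ap <- average_precision(pr_curve(m$tp, n_gt))
    oap <- oracle_ap101(m$tp, n_gt)
    ok <- ok && (is.na(ap) && is.na(oap) ||
                   isTRUE(all.equal(ap, oap, tolerance = 1e-12)))
  }
  expect_true(ok)
})

test_that("cumulative PR curve matches the hand-computed example", {
  pr <- pr_curve(c(TRUE, FALSE, TRUE), n_gt = 2)
  expect_equal(pr$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(pr$recall, c(1 / 2, 1 / 2, 1))
  pr2 <- pr_curve(rep(TRUE, 4), n_gt = 4)
  expect_equal(pr2$precision[4], 1)
  expect_equal(pr2$recall[4], 1)
  expect_equal(pr_curve(c(rep(TRUE, 8), rep(FALSE, 2)), 20)$precision[10], 0.8)
  expect_error(pr_curve(c(TRUE), n_gt = 0), "zero ground truth")
})

test_that("average precision covers the boundary cases", {
  expect_equal(average_precision(pr_curve(rep(TRUE, 3), 3)), 1.0)
  expect_equal(average_precision(pr_curve(FALSE, 1)), 0.0)
  expect_true(is.na(average_precision(pr_curve(logical(0), 0))))
  # worked 3-detection example against the independent oracle
  flags <- c(TRUE, FALSE, TRUE)
  expect_equal(average_precision(pr_curve(flags, 2)), oracle_ap101(flags, 2))
})

test_that("AP depends only on confidence ranks and responds to edits sanely", {
  set.seed(32)
  for (trial in 1:20) {
    sc <- random_scene()
    if (!nrow(sc$dets)) next
    m <- match_detections(sc$dets, sc$gts, 0.5)
    ap <- average_precision(pr_curve(m$tp, nrow(sc$gts)))
    # monotone transform of confidences preserves ranks hence AP
    sc2 <- sc
    sc2$dets$confidence <- plogis(3 * sc2$dets$confidence - 1)
    m2 <- match_detections(sc2$dets, sc2$gts, 0.5)
    expect_equal(average_precision(pr_curve(m2$tp, nrow(sc$gts))), ap)
    if (is.na(ap)) next
    # an extra FP below all confidences never increases AP
    expect_lte(average_precision(pr_curve(c(m$tp, FALSE), nrow(sc$gts))), ap)
    # an extra TP at top never decreases it (one more GT to cover)
    expect_gte(average_precision(pr_curve(c(TRUE, m$tp), nrow(sc$gts) + 1)),
               ap - 1e-12)
  }
})

test_that("mAP is the arithmetic mean over classes with defined AP", {
  expect_equal(map_summary(c(0.773, 0.868, 0.810))$map50, 0.817)
  expect_equal(map_summary(c(0.772, 0.867, 0.776))$map50, 0.805)
  expect_equal(map_summary(c(NA, 0.6))$map50, 0.6)
  expect_equal(map_summary(0.42)$map50, 0.42)
  expect_error(map_summary(c(NA_real_, NA_real_)), "defined")
})

test_that("F1 formula and argmax threshold behave", {
  # P = R = 0.8 -> F1 = 0.8 ; P = 1, R = 0 -> 0 ; P = .9, R = .6 -> .72
  f1 <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0
  expect_equal(f1(0.8, 0.8), 0.8)
  expect_equal(f1(1, 0), 0)
  expect_equal(f1(0.9, 0.6), 0.72)
  gt <- data.frame(image_id = 1, class_id = 0L, x1 = 0, y1 = 0, x2 = 10,
                   y2 = 10)
  dets <- data.frame(image_id = 1, class_id = 0L, x1 = 0, y1 = 0, x2 = 10,
                     y2 = 10, confidence = 0.7)
  fv <- f1_vs_confidence(dets, gt, num_classes = 1)
  expect_equal(max(fv$mean_f1), 1)
  expect_lte(fv$best_threshold, 0.7)
  expect_equal(fv$f1[1, fv$grid > 0.7], rep(0, sum(fv$grid > 0.7)))
})

test_that("confusion matrix normalizes ground-truth columns", {
  gts <- data.frame(image_id = c(1, 1, 2), class_id = c(0L, 1L, 2L),
                    x1 = c(0, 20, 0), y1 = c(0, 20, 0),
                    x2 = c(10, 30, 10), y2 = c(10, 30, 10))
  # det 1 correct; det 2 misclassified (predicts 0 on class-1 GT);
  # det 3 background FP; class-2 GT missed entirely
  dets <- data.frame(image_id = c(1, 1, 1), class_id = c(0L, 0L, 2L),
                     x1 = c(0, 20, 50), y1 = c(0, 20, 50),
                     x2 = c(10, 30, 60), y2 = c(10, 30, 60),
                     confidence = c(0.9, 0.8, 0.7))
  cm <- confusion_matrix_normalized(dets, gts, conf_thresh = 0.25,
                                    iou_thresh = 0.45, num_classes = 3)
  raw <- attr(cm, "raw")
  expect_equal(raw[1, 1], 1)  # class0 -> class0
  expect_equal(raw[1, 2], 1)  # class0 predicted on class1 GT
  expect_equal(raw[4, 3], 1)  # class2 GT missed -> background row
  expect_equal(raw[3, 4], 1)  # class2 FP -> background column
  for (j in 1:3) expect_equal(sum(cm[, j]), 1, tolerance = 1e-9)
})

test_that("all detections correct yields the identity class block", {
  gts <- data.frame(image_id = 1:3, class_id = 0:2,
                    x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  dets <- cbind(gts, confidence = 0.9)
  cm <- confusion_matrix_normalized(dets, gts, num_classes = 3)
  expect_equal(unname(cm[1:3, 1:3]), diag(3))
  # no detections: class columns collapse into the background row
  cm2 <- confusion_matrix_normalized(dets[0, ], gts, num_classes = 3)
  expect_equal(unname(cm2[4, 1:3]), rep(1, 3))
})

test_that("end-to-end evaluation summary is internally consistent", {
  set.seed(33)
  gts <- do.call(rbind, lapply(1:6, function(im) {
    data.frame(image_id = im, class_id = (im - 1) %% 3,
               x1 = 10, y1 = 10, x2 = 40, y2 = 40)
  }))
  jit <- function(b, d) transform(b, x1 = x1 + d, x2 = x2 + d)
  dets <- rbind(cbind(jit(gts[1:4, ], 2), confidence = runif(4, 0.6, 0.9)),
                cbind(transform(gts[5:6, ], x1 = 60, x2 = 90),
                      confidence = c(0.5, 0.4)))
  ev <- evaluate_detections(dets, gts, num_classes = 3)
  expect_s3_class(ev, "fracdet_eval")
  expect_equal(ev$map50, mean(ev$per_class$ap50))
  expect_true(all(ev$per_class$ap50 >= ev$per_class$ap50_95 - 1e-12))
  expect_true(all(ev$per_class$precision >= 0 & ev$per_class$precision <= 1))
})
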