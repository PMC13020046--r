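# Detection metrics: precision, recall, AP (101-point interpolated on the
# precision envelope), mAP50 and mAP50:95, F1-confidence curves and the
# ground-truth-normalized confusion matrix with a background row/column.

#' Intersection-over-union of two pixel boxes
#'
#' @param a,b boxes `c(x1, y1, x2, y2)` with `x1 < x2`, `y1 < y2`.
#' @return IoU in `[0, 1]`; symmetric in its arguments.
#' @export
iou_xyxy <- function(a, b) {
  if (a[1] >= a[3] || a[2] >= a[4] || b[1] >= b[3] || b[2] >= b[4]) {
    stop("degenerate box (x1 >= x2 or y1 >= y2)")
  }
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  ab <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (aa + ab - inter)
}

#' Greedy one-to-one matching of detections to ground truth
#'
#' Detections are taken in order of descending confidence (ties broken by
#' input order); each matches the highest-IoU not-yet-matched ground-truth
#' box of the same class with IoU at or above the threshold (IoU ties broken
#' by first ground-truth index) and becomes a true positive, otherwise a
#' false positive. Unmatched ground truth counts as false negatives.
#'
#' @param dets data.frame `class_id, x1, y1, x2, y2, confidence`.
#' @param gts data.frame `class_id, x1, y1, x2, y2`.
#' @param iou_thresh matching threshold.
#' @return list: `tp` (logical per detection, in confidence order),
#'   `order` (row indices of `dets` in that order), `gt_matched` (logical
#'   per ground-truth row), `n_tp`, `n_fp`, `n_fn`.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  nd <- nrow(dets)
  ng <- nrow(gts)
  ord <- if (nd) order(-dets$confidence) else integer(0)
  tp <- logical(nd)
  gt_matched <- logical(ng)
  for (k in seq_len(nd)) {
    i <- ord[k]
    best_iou <- -1
    best_j <- 0L
    for (j in seq_len(ng)) {
      if (gt_matched[j] || gts$class_id[j] != dets$class_id[i]) next
      v <- iou_xyxy(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                    as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
      if (v > best_iou) {
        best_iou <- v
        best_j <- j
      }
    }
    if (best_j > 0L && best_iou >= iou_thresh) {
      tp[k] <- TRUE
      gt_matched[best_j] <- TRUE
    }
  }
  list(tp = tp, order = ord, gt_matched = gt_matched,
       n_tp = sum(tp), n_fp = nd - sum(tp), n_fn = ng - sum(gt_matched))
}

#' Cumulative precision-recall curve
#'
#' @param tp logical flags of confidence-sorted detections.
#' @param n_gt number of ground-truth boxes.
#' @return list `precision`, `recall` (cumulative, same length as `tp`),
#'   `n_gt`.
#' @export
pr_curve <- function(tp, n_gt) {
  if (n_gt < 0) stop("n_gt must be >= 0")
  if (n_gt == 0 && any(tp)) stop("true positives reported with zero ground truth")
  k <- seq_along(tp)
  ctp <- cumsum(tp)
  list(precision = if (length(tp)) ctp / k else numeric(0),
       recall = if (length(tp)) {
         if (n_gt > 0) ctp / n_gt else rep(0, length(tp))
       } else numeric(0),
       n_gt = n_gt)
}

#' Average precision by 101-point interpolation
#'
#' Area under the monotone precision envelope of the PR curve, sampled at
#' recalls `0, 0.01, ..., 1`. With zero ground truth the AP is undefined
#' and `NA` is returned (such classes are excluded from mAP means).
#'
#' @param curve result of [pr_curve()].
#' @return AP in `[0, 1]`, or `NA` if undefined.
#' @export
average_precision <- function(curve) {
  if (curve$n_gt == 0) return(NA_real_)
  if (!length(curve$recall)) return(0)
  r <- curve$recall
  p <- curve$precision
  # precision envelope: best precision at recall >= r
  env <- rev(cummax(rev(p)))
  grid <- seq(0, 1, by = 0.01)
  vals <- vapply(grid, function(g) {
    i <- which(r >= g)
    if (length(i)) env[i[1]] else 0
  }, numeric(1))
  mean(vals)
}

#' Per-class and overall detection metrics
#'
#' Matches detections to ground truth per class at IoU 0.5 and at the
#' 0.50:0.05:0.95 grid, and aggregates AP into mAP by the arithmetic mean
#' over classes with ground truth. Reported per-class precision and recall
#' are taken at the confidence maximizing the class F1 score.
#'
#' @param dets data.frame `image_id, class_id, x1, y1, x2, y2, confidence`.
#' @param gts data.frame `image_id, class_id, x1, y1, x2, y2`.
#' @param num_classes number of classes.
#' @return a `fracdet_eval` list: `per_class` data.frame (`class_id`, `n_gt`,
#'   `precision`, `recall`, `ap50`, `ap50_95`), `precision`, `recall`,
#'   `map50`, `map50_95` (means over classes with ground truth).
#' @export
evaluate_detections <- function(dets, gts, num_classes = 3) {
  iou_grid <- seq(0.5, 0.95, by = 0.05)
  per <- lapply(seq_len(num_classes) - 1L, function(cl) {
    gc <- gts[gts$class_id == cl, , drop = FALSE]
    dc <- dets[dets$class_id == cl, , drop = FALSE]
    n_gt <- nrow(gc)
    aps <- vapply(iou_grid, function(th) {
      flags <- match_flags_over_images(dc, gc, th)
      average_precision(pr_curve(flags$tp, n_gt))
    }, numeric(1))
    f <- match_flags_over_images(dc, gc, 0.5)
    pr <- pr_curve(f$tp, n_gt)
    best <- best_f1_point(pr, f$conf)
    data.frame(class_id = cl, n_gt = n_gt,
               precision = best$precision, recall = best$recall,
               ap50 = aps[1], ap50_95 = mean(aps))
  })
  per <- do.call(rbind, per)
  ok <- per$n_gt > 0
  if (!any(ok)) stop("no class has ground truth; metrics undefined")
  structure(list(per_class = per,
                 precision = mean(per$precision[ok]),
                 recall = mean(per$recall[ok]),
                 map50 = mean(per$ap50[ok]),
                 map50_95 = mean(per$ap50_95[ok])),
            class = "fracdet_eval")
}

#' @export
print.fracdet_eval <- function(x, ...) {
  cat(sprintf("<eval> P %.3f R %.3f mAP50 %.3f mAP50:95 %.3f\n",
              x$precision, x$recall, x$map50, x$map50_95))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

# Match one class's detections image by image; returns confidence-sorted
# TP flags and confidences across the whole set.
match_flags_over_images <- function(dc, gc, iou_thresh) {
  if (!nrow(dc)) return(list(tp = logical(0), conf = numeric(0)))
  flags <- logical(0)
  confs <- numeric(0)
  for (im in unique(dc$image_id)) {
    di <- dc[dc$image_id == im, , drop = FALSE]
    gi <- gc[gc$image_id == im, , drop = FALSE]
    m <- match_detections(di, gi, iou_thresh)
    flags <- c(flags, m$tp)
    confs <- c(confs, di$confidence[m$order])
  }
  o <- order(-confs)
  list(tp = flags[o], conf = confs[o])
}

best_f1_point <- function(pr, conf) {
  if (!length(pr$precision)) {
    return(list(precision = 0, recall = 0, f1 = 0, conf = NA_real_))
  }
  f1 <- ifelse(pr$precision + pr$recall > 0,
               2 * pr$precision * pr$recall / (pr$precision + pr$recall), 0)
  i <- which.max(f1)
  list(precision = pr$precision[i], recall = pr$recall[i], f1 = f1[i],
       conf = conf[i])
}

#' Mean average precision from per-class APs
#'
#' The overall mAP is the arithmetic mean of the per-class average
#' precisions over classes with defined AP.
#'
#' @param ap50 per-class AP at IoU 0.5 (NA = undefined).
#' @param ap50_95 optional per-class AP averaged over the 0.50:0.05:0.95
#'   grid.
#' @return list `map50` (and `map50_95` if supplied).
#' @export
map_summary <- function(ap50, ap50_95 = NULL) {
  if (all(is.na(ap50))) stop("no class has a defined AP")
  out <- list(map50 = mean(ap50, na.rm = TRUE))
  if (!is.null(ap50_95)) out$map50_95 <- mean(ap50_95, na.rm = TRUE)
  out
}

#' F1 score over a confidence grid
#'
#' Computes `F1 = 2PR / (P + R)` per class and per grid point (0 where
#' `P + R = 0`), the class-mean curve and the best threshold.
#'
#' @param dets,gts as in [evaluate_detections()].
#' @param grid confidence thresholds in `[0, 1]`.
#' @param iou_thresh matching threshold.
#' @param num_classes number of classes.
#' @return list: `grid`, `f1` (classes x grid matrix), `mean_f1`,
#'   `best_threshold` (argmax of the mean curve).
#' @export
f1_vs_confidence <- function(dets, gts, grid = seq(0, 1, by = 0.01),
                             iou_thresh = 0.5, num_classes = 3) {
  if (any(grid < 0 | grid > 1)) stop("grid must lie in [0, 1]")
  f1 <- matrix(0, num_classes, length(grid))
  for (cl in seq_len(num_classes) - 1L) {
    gc <- gts[gts$class_id == cl, , drop = FALSE]
    dc <- dets[dets$class_id == cl, , drop = FALSE]
    mf <- match_flags_over_images(dc, gc, iou_thresh)
    for (k in seq_along(grid)) {
      keep <- mf$conf >= grid[k]
      tp <- sum(mf$tp[keep])
      fp <- sum(keep) - tp
      fn <- nrow(gc) - tp
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1[cl + 1, k] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    }
  }
  mean_f1 <- colMeans(f1)
  list(grid = grid, f1 = f1, mean_f1 = mean_f1,
       best_threshold = grid[which.max(mean_f1)])
}

#' Ground-truth-normalized confusion matrix
#'
#' Detections above `conf_thresh` are matched to ground truth across classes
#' at `iou_thresh` (greedy by confidence). Matched pairs increment cell
#' (predicted class, true class); unmatched ground truth goes to the
#' background row, unmatched detections to the background column. Columns
#' (true classes) with support are normalized to sum to one.
#'
#' @param dets,gts as in [evaluate_detections()].
#' @param conf_thresh,iou_thresh thresholds.
#' @param num_classes number of classes.
#' @return `(num_classes + 1) x (num_classes + 1)` matrix (last index =
#'   background), columns normalized; `attr(, "raw")` holds the counts.
#' @export
confusion_matrix_normalized <- function(dets, gts, conf_thresh = 0.25,
                                        iou_thresh = 0.45, num_classes = 3) {
  stopifnot(conf_thresh >= 0, conf_thresh <= 1, iou_thresh >= 0, iou_thresh <= 1)
  k <- num_classes + 1L
  cm <- matrix(0, k, k)
  labs <- c(paste0("class", seq_len(num_classes) - 1L), "background")
  dimnames(cm) <- list(pred = labs, true = labs)
  dets <- dets[dets$confidence >= conf_thresh, , drop = FALSE]
  ids <- union(unique(dets$image_id), unique(gts$image_id))
  for (im in ids) {
    di <- dets[dets$image_id == im, , drop = FALSE]
    gi <- gts[gts$image_id == im, , drop = FALSE]
    nd <- nrow(di)
    ng <- nrow(gi)
    ord <- if (nd) order(-di$confidence) else integer(0)
    gdone <- logical(ng)
    ddone <- logical(nd)
    for (ii in ord) {
      best <- 0L
      best_iou <- -1
      for (j in seq_len(ng)) {
        if (gdone[j]) next
        v <- iou_xyxy(as.numeric(di[ii, c("x1", "y1", "x2", "y2")]),
                      as.numeric(gi[j, c("x1", "y1", "x2", "y2")]))
        if (v >= iou_thresh && v > best_iou) {
          best <- j
          best_iou <- v
        }
      }
      if (best > 0L) {
        cm[di$class_id[ii] + 1L, gi$class_id[best] + 1L] <-
          cm[di$class_id[ii] + 1L, gi$class_id[best] + 1L] + 1
        gdone[best] <- TRUE
        ddone[ii] <- TRUE
      }
    }
    for (j in which(!gdone)) {
      cm[k, gi$class_id[j] + 1L] <- cm[k, gi$class_id[j] + 1L] + 1
    }
    for (ii in which(!ddone)) {
      cm[di$class_id[ii] + 1L, k] <- cm[di$class_id[ii] + 1L, k] + 1
    }
  }
  raw <- cm
  for (j in seq_len(k)) {
    s <- sum(cm[, j])
    if (s > 0) cm[, j] <- cm[, j] / s
  }
  attr(cm, "raw") <- raw
  cm
}
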