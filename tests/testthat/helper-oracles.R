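# Independent reference implementations used as oracles. These are written
# as direct transcriptions of the definitions (plain loops, no shared code
# with the package internals).

oracle_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# Greedy confidence-ordered one-to-one matching, re-derived from scratch.
oracle_match <- function(dets, gts, thr) {
  ord <- order(-dets$confidence)
  used <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(dets))
  for (i in ord) {
    cand <- which(!used & gts$class_id == dets$class_id[i])
    if (!length(cand)) next
    ious <- sapply(cand, function(j) {
      oracle_iou(c(dets$x1[i], dets$y1[i], dets$x2[i], dets$y2[i]),
                 c(gts$x1[j], gts$y1[j], gts$x2[j], gts$y2[j]))
    })
    jbest <- cand[which.max(ious)]
    if (max(ious) >= thr) {
      tp[i] <- TRUE
      used[jbest] <- TRUE
    }
  }
  tp[ord]
}

# 101-point interpolated AP computed directly from the definition.
oracle_ap101 <- function(tp_sorted, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (!length(tp_sorted)) return(0)
  prec <- cumsum(tp_sorted) / seq_along(tp_sorted)
  rec <- cumsum(tp_sorted) / n_gt
  total <- 0
  for (g in seq(0, 1, by = 0.01)) {
    # interpolated precision: best precision at any recall >= g
    total <- total + if (any(rec >= g)) max(prec[rec >= g]) else 0
  }
  total / 101
}

# random detection scene for equivalence testing
random_scene <- function(max_boxes = 10, num_classes = 3) {
  ng <- sample(0:max_boxes, 1)
  nd <- sample(0:max_boxes, 1)
  mkbox <- function(n) {
    x1 <- runif(n, 0, 80)
    y1 <- runif(n, 0, 80)
    data.frame(x1 = x1, y1 = y1, x2 = x1 + runif(n, 2, 30),
               y2 = y1 + runif(n, 2, 30))
  }
  gts <- cbind(data.frame(class_id = sample(0:(num_classes - 1), ng,
                                            replace = TRUE)), mkbox(ng))
  dets <- cbind(data.frame(class_id = sample(0:(num_classes - 1), nd,
                                             replace = TRUE)), mkbox(nd),
                data.frame(confidence = round(runif(nd), 3)))
  list(dets = dets, gts = gts)
}

# brute-force parameter count: enumerate every learnable array in the model
oracle_param_count <- function(model) {
  tot <- 0
  for (p in model$params) {
    for (nm in c("w", "b", "gamma", "beta")) {
      if (!is.null(p[[nm]])) tot <- tot + length(p[[nm]])
    }
  }
  tot
}

make_phantom_items <- function(n, imgsz = 160, seed = 1,
                               classes = rep(0:2, length.out = n)) {
  cfg <- phantom_config(imgsz = imgsz, seed = seed)
  set.seed(seed)
  lapply(classes, function(cl) {
    ex <- generate_example(cfg, cl)
    list(image = ex$image, labels = ex$label)
  })
}
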