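# Training objective: class weights, losses, assignment, schedule, loop.

test_that("inverse-frequency class weights penalize minority classes", {
  w <- class_weights_from_counts(c(261, 579, 136))
  expect_equal(mean(w), 1)
  expect_true(w[3] > w[1] && w[1] > w[2])  # A3 > A1 > A2
  expect_equal(class_weights_from_counts(c(100, 100, 100)), c(1, 1, 1))
  expect_equal(class_weights_from_counts(c(1, 2)), c(4 / 3, 2 / 3))
  expect_error(class_weights_from_counts(c(10, 0, 5)), "positive")
  # scale invariance
  expect_equal(class_weights_from_counts(c(3, 7, 11)),
               class_weights_from_counts(2 * c(3, 7, 11)))
})

test_that("weighted BCE matches its closed forms", {
  z <- matrix(0, 4, 3)  # sigmoid = 0.5 everywhere
  t01 <- matrix(rep(c(1, 0, 1), each = 4), 4, 3)
  expect_equal(classification_loss(z, t01), 12 * log(2) / max(sum(t01), 1))
  # saturated perfect predictions
  zp <- matrix(ifelse(t01 > 0.5, 40, -40), 4, 3)
  expect_lt(classification_loss(zp, t01), 1e-10)
  # doubling one class's weight adds exactly that class's BCE share again
  base <- classification_loss(z, t01, c(1, 1, 1))
  d <- classification_loss(z, t01, c(1, 2, 1)) - base
  expect_equal(d, 4 * log(2) / sum(t01))
  expect_error(classification_loss(z, t01 * 2), "\\[0, 1\\]")
})

test_that("CIoU and DFL losses hit their analytic anchors", {
  b <- matrix(c(0, 0, 10, 10), 1)
  reg_max <- 16
  onehot <- array(0, c(1, 4, reg_max))
  k <- 5
  onehot[1, , k + 1] <- 60  # one-hot logit mass at bin k for each edge
  r <- box_and_dfl_loss(b, onehot, b, centers = matrix(c(5, 5), 1), stride = 1)
  expect_equal(r$box_loss, 0, tolerance = 1e-12)
  expect_equal(r$dfl_loss, 0, tolerance = 1e-6)
  # uniform distribution against the integer target: ln(reg_max)
  unif <- array(0, c(1, 4, reg_max))
  r2 <- box_and_dfl_loss(b, unif, b, centers = matrix(c(5, 5), 1), stride = 1)
  expect_equal(r2$dfl_loss, log(reg_max), tolerance = 1e-9)
  expect_error(box_and_dfl_loss(matrix(c(5, 5, 5, 10), 1), onehot, b),
               "degenerate")
})

test_that("CIoU gradients track finite differences (alpha detached)", {
  set.seed(41)
  for (trial in 1:30) {
    p <- c(sort(runif(2, 0, 20)), sort(runif(2, 0, 20)))[c(1, 3, 2, 4)]
    g <- c(sort(runif(2, 0, 20)), sort(runif(2, 0, 20)))[c(1, 3, 2, 4)]
    p[3:4] <- p[3:4] + 0.5
    g[3:4] <- g[3:4] + 0.5
    cg <- fracdet:::ciou_with_grad(matrix(p, 1), matrix(g, 1))
    for (e in 1:4) {
      eps <- 1e-6
      pp <- p; pp[e] <- pp[e] + eps
      pm <- p; pm[e] <- pm[e] - eps
      num <- (fracdet:::ciou_with_grad(matrix(pp, 1), matrix(g, 1))$ciou -
                fracdet:::ciou_with_grad(matrix(pm, 1), matrix(g, 1))$ciou) /
        (2 * eps)
      expect_equal(cg$grad[e], num, tolerance = 0.1)
    }
  }
})

test_that("target assignment follows center gating and IoU tie-breaks", {
  # 4x4 grid of stride-1 cells
  centers <- as.matrix(expand.grid(cx = (1:4) - 0.5, cy = (1:4) - 0.5))
  ncell <- nrow(centers)
  boxes <- cbind(centers[, 1] - 0.5, centers[, 2] - 0.5,
                 centers[, 1] + 0.5, centers[, 2] + 0.5)
  scores <- matrix(0.5, ncell, 2)
  # no ground truth: empty assignment, all-zero targets
  a0 <- assign_targets(scores, boxes, matrix(0, 0, 4), integer(0), centers)
  expect_length(a0$fg_idx, 0)
  expect_equal(sum(a0$target_scores), 0)
  # one box covering exactly one cell center
  g1 <- matrix(c(0.1, 0.1, 0.9, 0.9), 1)
  a1 <- assign_targets(scores, boxes, g1, 0L, centers)
  expect_equal(a1$fg_idx, which(centers[, 1] == 0.5 & centers[, 2] == 0.5))
  # two overlapping boxes competing for one cell: higher IoU wins
  gA <- c(0, 0, 1, 1)      # IoU 1 with cell (0.5, 0.5) box
  gB <- c(0, 0, 2, 2)      # larger, lower IoU with that cell's box
  a2 <- assign_targets(scores, boxes, rbind(gA, gB), c(0L, 1L), centers)
  cell11 <- which(centers[, 1] == 0.5 & centers[, 2] == 0.5)
  expect_true(cell11 %in% a2$fg_idx)
  expect_equal(a2$gt_idx[match(cell11, a2$fg_idx)], 1L)
  # brute-force check of the winner on every contested cell
  for (k in seq_along(a2$fg_idx)) {
    i <- a2$fg_idx[k]
    iA <- oracle_iou(boxes[i, ], gA)
    iB <- oracle_iou(boxes[i, ], gB)
    inA <- centers[i, 1] > gA[1] && centers[i, 1] < gA[3] &&
      centers[i, 2] > gA[2] && centers[i, 2] < gA[4]
    if (inA && iA >= iB) expect_equal(a2$gt_idx[k], 1L)
  }
})

test_that("cosine schedule spans lr0 to lr0*lrf and never increases", {
  cfg <- train_config(lr0 = 0.01, lrf = 0.01, epochs = 200)
  expect_equal(lr_schedule(0, cfg), 0.01)
  expect_equal(lr_schedule(199, cfg), 0.0001)
  mid <- lr_schedule(199 / 2, cfg)
  expect_equal(mid, (0.01 + 0.0001) / 2)
  lrs <- lr_schedule(0:199, cfg)
  expect_true(all(diff(lrs) <= 1e-15))
  expect_error(lr_schedule(200, cfg), "range")
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("detection loss is finite, non-negative and respects its total", {
  set.seed(43)
  m <- assemble_model(model_config(replacement_set = adown_default_sites()))
  x <- array(runif(96 * 96 * 3 * 2), c(96, 96, 3, 2))
  raw <- model_forward(m, x, train = TRUE)
  gt <- list(data.frame(class_id = 0L, x1 = 20, y1 = 20, x2 = 60, y2 = 60),
             data.frame(class_id = integer(0), x1 = numeric(0),
                        y1 = numeric(0), x2 = numeric(0), y2 = numeric(0)))
  cfg <- train_config(imgsz = 96)
  ls <- detection_loss(raw, gt, cfg, with_grads = TRUE)
  bd <- ls$breakdown
  for (v in unlist(bd)) {
    expect_true(is.finite(v))
    expect_gte(v, 0)
  }
  lw <- cfg$loss_weights
  expect_equal(bd$total, lw[["box"]] * bd$box_loss + lw[["cls"]] * bd$cls_loss
               + lw[["dfl"]] * bd$dfl_loss)
  for (lv in ls$grads) {
    expect_true(all(is.finite(lv$cls)))
    expect_true(all(is.finite(lv$box)))
  }
  # image without ground truth contributes no box/dfl gradient
  expect_equal(sum(abs(ls$grads$p8$box[, , , 2])), 0)
})

test_that("training is deterministic under a fixed seed", {
  items <- make_phantom_items(4, imgsz = 96, seed = 5)
  run <- function() {
    cfg <- train_config(imgsz = 96, batch_size = 4, epochs = 3,
                        augment = FALSE, seed = 7, max_iterations = 3)
    set.seed(7)
    m <- assemble_model(model_config(replacement_set = adown_default_sites()))
    train_loop(m, items, cfg)$log$total
  }
  l1 <- run()
  l2 <- run()
  expect_identical(l1, l2)
  expect_length(l1, 3)
  expect_error(train_loop(assemble_model(model_config()), list(),
                          train_config()), "dataset")
})
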