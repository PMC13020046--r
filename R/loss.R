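# Detection objective: class-weighted binary cross-entropy classification,
# CIoU box regression and distribution focal loss over reg_max bins, with
# task-aligned assignment of ground truth to grid cells. Gradients with
# respect to the head logits are derived analytically (softmax-expectation
# Jacobian for the DFL decode, closed-form CIoU derivatives with the
# trade-off coefficient treated as constant, as is customary).

#' Training configuration
#'
#' Defaults follow the customary recipe for this detector family: SGD with
#' momentum, cosine-annealed learning rate from `lr0` to `lr0 * lrf`, and
#' loss weights (box 7.5, cls 0.5, dfl 1.5).
#'
#' @param lr0 initial learning rate.
#' @param lrf final learning rate as a fraction of `lr0`.
#' @param batch_size images per gradient step.
#' @param epochs training epochs (>= 1).
#' @param weight_decay L2 penalty on convolution kernels.
#' @param momentum SGD momentum.
#' @param warmup_epochs linear learning-rate warmup span.
#' @param box,cls,dfl loss-component weights.
#' @param imgsz square input size (divisible by 32).
#' @param seed single seed from which all training randomness derives.
#' @param augment apply horizontal flip / HSV / mosaic augmentation.
#' @param mosaic probability of composing a 4-image mosaic per sample.
#' @param max_iterations optional cap on total gradient steps.
#' @param class_weights optional per-class loss weights (see
#'   [class_weights_from_counts()]); `NULL` means uniform.
#' @return a `fracdet_train_config`.
#' @export
train_config <- function(lr0 = 0.01, lrf = 0.01, batch_size = 16, epochs = 200,
                         weight_decay = 5e-4, momentum = 0.937,
                         warmup_epochs = 3, box = 7.5, cls = 0.5, dfl = 1.5,
                         imgsz = 640, seed = 0, augment = TRUE, mosaic = 1.0,
                         max_iterations = NULL, class_weights = NULL) {
  if (lr0 <= 0) stop("lr0 must be positive")
  if (lrf <= 0 || lrf > 1) stop("lrf must be in (0, 1]")
  if (epochs < 1) stop("epochs must be >= 1")
  if (imgsz %% 32 != 0) stop("imgsz must be divisible by 32")
  structure(list(lr0 = lr0, lrf = lrf, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 momentum = momentum, warmup_epochs = warmup_epochs,
                 loss_weights = c(box = box, cls = cls, dfl = dfl),
                 imgsz = as.integer(imgsz), seed = as.integer(seed),
                 augment = augment, mosaic = mosaic,
                 max_iterations = max_iterations,
                 class_weights = class_weights),
            class = "fracdet_train_config")
}

#' Inverse-frequency class weights
#'
#' Weights proportional to `1 / count`, normalized to mean one, so minority
#' classes (e.g. A3 and A1 fractures in an imbalanced clinical set) receive
#' strictly larger loss penalties. Scale-invariant in the counts.
#'
#' @param counts positive per-class instance counts.
#' @return numeric weight vector with mean 1.
#' @export
class_weights_from_counts <- function(counts) {
  if (any(counts <= 0)) stop("all class counts must be positive")
  w <- 1 / counts
  w <- w / mean(w)
  unname(w)
}

#' Cosine learning-rate schedule
#'
#' Cosine annealing from `lr0` at epoch 0 to `lr0 * lrf` at the final epoch.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @param config a [train_config()].
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, config) {
  if (any(epoch < 0) || any(epoch >= config$epochs)) {
    stop("epoch out of range [0, epochs)")
  }
  if (config$epochs == 1L) return(rep(config$lr0, length(epoch)))
  frac <- epoch / (config$epochs - 1)
  config$lr0 * (config$lrf + (1 - config$lrf) * 0.5 * (1 + cos(pi * frac)))
}

#' Weighted binary cross-entropy classification loss
#'
#' Per-class-weighted BCE between sigmoid(logits) and soft target scores,
#' summed over all cells and classes and normalized by the total assigned
#' target score (floored at 1).
#'
#' @param pred_logits matrix (cells x classes) of raw logits.
#' @param target_scores matrix of the same shape, values in `[0, 1]`.
#' @param weights per-class weights (default uniform).
#' @return scalar loss.
#' @export
classification_loss <- function(pred_logits, target_scores, weights = NULL) {
  pred_logits <- as.matrix(pred_logits)
  target_scores <- as.matrix(target_scores)
  stopifnot(identical(dim(pred_logits), dim(target_scores)))
  if (any(target_scores < 0 | target_scores > 1)) {
    stop("target scores must lie in [0, 1]")
  }
  nc <- ncol(pred_logits)
  if (is.null(weights)) weights <- rep(1, nc)
  # numerically stable BCE-with-logits
  z <- pred_logits
  t <- target_scores
  bce <- pmax(z, 0) - z * t + log1p(exp(-abs(z)))
  norm <- max(sum(t), 1)
  sum(sweep(bce, 2, weights, "*")) / norm
}

#' Complete-IoU between box pairs, with gradients
#'
#' @param pred,target matrices (n x 4) of pixel `x1, y1, x2, y2` boxes.
#' @return list: `ciou` (length n) and `grad` (n x 4, d ciou / d pred).
#' @keywords internal
ciou_with_grad <- function(pred, target) {
  pred <- matrix(pred, ncol = 4)
  target <- matrix(target, ncol = 4)
  if (any(pred[, 1] >= pred[, 3]) || any(pred[, 2] >= pred[, 4]) ||
      any(target[, 1] >= target[, 3]) || any(target[, 2] >= target[, 4])) {
    stop("degenerate box (x1 >= x2 or y1 >= y2)")
  }
  px1 <- pred[, 1]; py1 <- pred[, 2]; px2 <- pred[, 3]; py2 <- pred[, 4]
  gx1 <- target[, 1]; gy1 <- target[, 2]; gx2 <- target[, 3]; gy2 <- target[, 4]
  w <- px2 - px1; h <- py2 - py1
  wg <- gx2 - gx1; hg <- gy2 - gy1
  ix1 <- pmax(px1, gx1); iy1 <- pmax(py1, gy1)
  ix2 <- pmin(px2, gx2); iy2 <- pmin(py2, gy2)
  iw <- pmax(ix2 - ix1, 0); ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  ap <- w * h; ag <- wg * hg
  uni <- ap + ag - inter
  iou <- inter / uni
  # enclosing box
  cw <- pmax(px2, gx2) - pmin(px1, gx1)
  chh <- pmax(py2, gy2) - pmin(py1, gy1)
  c2 <- cw^2 + chh^2 + 1e-9
  pcx <- (px1 + px2) / 2; pcy <- (py1 + py2) / 2
  gcx <- (gx1 + gx2) / 2; gcy <- (gy1 + gy2) / 2
  rho2 <- (pcx - gcx)^2 + (pcy - gcy)^2
  dang <- atan(wg / hg) - atan(w / h)
  v <- (4 / pi^2) * dang^2
  alpha <- v / (1 - iou + v + 1e-9)  # treated as constant in the gradient
  ciou <- iou - rho2 / c2 - alpha * v

  act <- iw > 0 & ih > 0
  # d inter
  dI <- matrix(0, nrow(pred), 4)
  dI[, 1] <- -ih * (px1 > gx1) * act
  dI[, 2] <- -iw * (py1 > gy1) * act
  dI[, 3] <- ih * (px2 < gx2) * act
  dI[, 4] <- iw * (py2 < gy2) * act
  dAp <- cbind(-h, -w, h, w)
  dU <- dAp - dI
  dIoU <- (dI * uni - inter * dU) / uni^2
  # d rho2, d c2
  dRho <- cbind(pcx - gcx, pcy - gcy, pcx - gcx, pcy - gcy)
  dC2 <- cbind(-2 * cw * (px1 < gx1), -2 * chh * (py1 < gy1),
               2 * cw * (px2 > gx2), 2 * chh * (py2 > gy2))
  dPen <- (dRho * c2 - rho2 * dC2) / c2^2
  # d v through w, h
  dv_dw <- -(8 / pi^2) * dang * h / (w^2 + h^2)
  dv_dh <- (8 / pi^2) * dang * w / (w^2 + h^2)
  dV <- cbind(-dv_dw, -dv_dh, dv_dw, dv_dh)
  grad <- dIoU - dPen - alpha * dV
  list(ciou = ciou, grad = grad)
}

#' CIoU box loss and distribution focal loss
#'
#' `box_loss` is `1 - CIoU` averaged over the pairs. `dfl_loss` is the
#' cross-entropy of each predicted per-edge bin distribution against the two
#' integer bins bracketing the target distance, linearly weighted, averaged
#' over edges and pairs.
#'
#' @param pred_boxes matrix (n x 4) pixel `x1, y1, x2, y2`.
#' @param pred_dists array (n x 4 x reg_max) of bin logits per box edge.
#' @param target_boxes matrix (n x 4) ground-truth boxes.
#' @param centers matrix (n x 2) of cell centers (pixels); defaults to the
#'   target box centers.
#' @param stride pixels per distance unit (scalar or length n).
#' @return list `(box_loss, dfl_loss)`.
#' @export
box_and_dfl_loss <- function(pred_boxes, pred_dists, target_boxes,
                             centers = NULL, stride = 1) {
  pred_boxes <- matrix(pred_boxes, ncol = 4)
  target_boxes <- matrix(target_boxes, ncol = 4)
  n <- nrow(pred_boxes)
  reg_max <- dim(pred_dists)[3]
  if (is.null(dim(pred_dists)) || dim(pred_dists)[2] != 4) {
    stop("pred_dists must be an (n x 4 x reg_max) array")
  }
  cg <- ciou_with_grad(pred_boxes, target_boxes)
  box_loss <- mean(1 - cg$ciou)
  if (is.null(centers)) {
    centers <- cbind((target_boxes[, 1] + target_boxes[, 3]) / 2,
                     (target_boxes[, 2] + target_boxes[, 4]) / 2)
  }
  tdist <- target_ltrb(target_boxes, centers) / stride
  tdist <- pmin(pmax(tdist, 0), reg_max - 1 - 0.01)
  dfl <- 0
  for (e in 1:4) {
    z <- matrix(pred_dists[, e, ], n, reg_max)
    p <- softmax_rows(z)
    tl <- floor(tdist[, e])
    wl <- tl + 1 - tdist[, e]
    wr <- tdist[, e] - tl
    pl <- p[cbind(seq_len(n), tl + 1)]
    pr <- p[cbind(seq_len(n), pmin(tl + 2, reg_max))]
    dfl <- dfl + mean(-(wl * log(pmax(pl, 1e-12)) + wr * log(pmax(pr, 1e-12))))
  }
  list(box_loss = box_loss, dfl_loss = dfl / 4)
}

target_ltrb <- function(boxes, centers) {
  cbind(centers[, 1] - boxes[, 1], centers[, 2] - boxes[, 2],
        boxes[, 3] - centers[, 1], boxes[, 4] - centers[, 2])
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Task-aligned assignment of ground truth to grid cells
#'
#' Each ground-truth box is assigned to its `topk` candidate cells by the
#' alignment metric `score^alpha * IoU^beta`, where candidates are cells
#' whose center lies inside the box; a cell claimed by several boxes goes to
#' the one with the highest IoU. Soft classification targets are the
#' alignment metric rescaled per box to peak at that box's best IoU.
#'
#' @param pred_scores matrix (cells x classes) of class probabilities.
#' @param pred_boxes matrix (cells x 4) decoded pixel boxes.
#' @param gt_boxes matrix (g x 4) ground-truth pixel boxes (may have 0 rows).
#' @param gt_classes integer vector (0-based class ids).
#' @param centers matrix (cells x 2) of cell-center pixel coordinates.
#' @param topk,alpha,beta assigner hyperparameters.
#' @return list: `fg_idx` (assigned cell indices), `gt_idx` (their box),
#'   `target_scores` (cells x classes soft targets), `target_boxes`
#'   (length(fg_idx) x 4).
#' @export
assign_targets <- function(pred_scores, pred_boxes, gt_boxes, gt_classes,
                           centers, topk = 10, alpha = 0.5, beta = 6) {
  ncell <- nrow(pred_scores)
  nc <- ncol(pred_scores)
  target_scores <- matrix(0, ncell, nc)
  g <- if (is.null(gt_boxes)) 0L else nrow(gt_boxes)
  if (g == 0L) {
    return(list(fg_idx = integer(0), gt_idx = integer(0),
                target_scores = target_scores,
                target_boxes = matrix(0, 0, 4)))
  }
  metric <- matrix(0, ncell, g)
  iou_m <- matrix(0, ncell, g)
  for (j in seq_len(g)) {
    inside <- centers[, 1] > gt_boxes[j, 1] & centers[, 1] < gt_boxes[j, 3] &
      centers[, 2] > gt_boxes[j, 2] & centers[, 2] < gt_boxes[j, 4]
    if (!any(inside)) next
    idx <- which(inside)
    ious <- iou_many(pred_boxes[idx, , drop = FALSE], gt_boxes[j, ])
    sc <- pred_scores[idx, gt_classes[j] + 1]
    iou_m[idx, j] <- ious
    metric[idx, j] <- pmax(sc, 0)^alpha * pmax(ious, 0)^beta
  }
  mask <- matrix(FALSE, ncell, g)
  for (j in seq_len(g)) {
    cand <- which(metric[, j] > 0)
    if (!length(cand)) {
      # degenerate: no positive-metric candidate; fall back to centers inside
      cand <- which(iou_m[, j] > 0 | (centers[, 1] > gt_boxes[j, 1] &
                                        centers[, 1] < gt_boxes[j, 3] &
                                        centers[, 2] > gt_boxes[j, 2] &
                                        centers[, 2] < gt_boxes[j, 4]))
      if (!length(cand)) next
    }
    take <- cand[order(-metric[cand, j])][seq_len(min(topk, length(cand)))]
    mask[take, j] <- TRUE
  }
  # resolve cells claimed by several boxes: highest IoU wins
  fg <- which(rowSums(mask) > 0)
  gt_of <- integer(length(fg))
  for (k in seq_along(fg)) {
    i <- fg[k]
    js <- which(mask[i, ])
    gt_of[k] <- js[which.max(iou_m[i, js])]
  }
  # normalized soft targets per ground-truth box
  for (j in seq_len(g)) {
    cells <- fg[gt_of == j]
    if (!length(cells)) next
    mmax <- max(metric[cells, j])
    imax <- max(iou_m[cells, j])
    t <- if (mmax > 0) metric[cells, j] / mmax * imax else rep(imax, length(cells))
    target_scores[cells, gt_classes[j] + 1] <- t
  }
  list(fg_idx = fg, gt_idx = gt_of, target_scores = target_scores,
       target_boxes = gt_boxes[gt_of, , drop = FALSE])
}

iou_many <- function(boxes, one) {
  ix1 <- pmax(boxes[, 1], one[1]); iy1 <- pmax(boxes[, 2], one[2])
  ix2 <- pmin(boxes[, 3], one[3]); iy2 <- pmin(boxes[, 4], one[4])
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  a1 <- pmax(boxes[, 3] - boxes[, 1], 0) * pmax(boxes[, 4] - boxes[, 2], 0)
  a2 <- (one[3] - one[1]) * (one[4] - one[2])
  inter / (a1 + a2 - inter + 1e-12)
}

# ---------------------------------------------------------------------------
# Full batch loss with gradients at the head outputs.

flatten_raw <- function(raw) {
  reg_max <- dim(raw[[1]]$box)[3] %/% 4L
  nc <- dim(raw[[1]]$cls)[3]
  n_img <- dim(raw[[1]]$box)[4]
  cls <- list(); box <- list(); centers <- list(); strides <- list()
  sizes <- list()
  for (lv in names(raw)) {
    L <- raw[[lv]]
    d <- dim(L$box)
    ncell <- d[1] * d[2]
    cls[[lv]] <- array(L$cls, c(ncell, nc, n_img))
    box[[lv]] <- array(L$box, c(ncell, reg_max, 4L, n_img))
    cy <- rep((seq_len(d[1]) - 0.5) * L$stride, times = d[2])
    cx <- rep((seq_len(d[2]) - 0.5) * L$stride, each = d[1])
    centers[[lv]] <- cbind(cx, cy)
    strides[[lv]] <- rep(L$stride, ncell)
    sizes[[lv]] <- d
  }
  list(cls = do.call(abind1, cls), box = do.call(abind1, box),
       centers = do.call(rbind, centers), stride = unlist(strides),
       sizes = sizes, reg_max = reg_max, nc = nc, n_img = n_img)
}

abind1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  tot <- sum(vapply(xs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(tot, d[-1]))
  off <- 0L
  ix <- lapply(d[-1], seq_len)
  for (a in xs) {
    n1 <- dim(a)[1]
    args <- c(list(out, (off + 1L):(off + n1)), ix, list(value = a))
    out <- do.call(`[<-`, args)
    off <- off + n1
  }
  out
}

#' Detection loss for a forward pass
#'
#' Computes the class-weighted BCE / CIoU / DFL objective for a batch and,
#' optionally, its analytic gradients with respect to the raw head outputs.
#'
#' @param raw output of [model_forward()].
#' @param gt list (length = batch) of data.frames with columns
#'   `class_id, x1, y1, x2, y2` in input pixels.
#' @param config a [train_config()] (loss weights, class weights).
#' @param with_grads also return per-level gradient arrays.
#' @return list: `breakdown` (`box_loss`, `cls_loss`, `dfl_loss`, `total`),
#'   plus `grads` when requested (named by head node, matching the raw
#'   layout).
#' @export
detection_loss <- function(raw, gt, config = train_config(), with_grads = FALSE) {
  fl <- flatten_raw(raw)
  nc <- fl$nc
  reg_max <- fl$reg_max
  n_img <- fl$n_img
  ncell <- nrow(fl$centers)
  cw <- config$class_weights
  if (is.null(cw)) cw <- rep(1, nc)
  lw <- config$loss_weights

  cls_loss <- 0; box_loss <- 0; dfl_loss <- 0
  dcls <- if (with_grads) array(0, c(ncell, nc, n_img)) else NULL
  dbox <- if (with_grads) array(0, c(ncell, reg_max, 4L, n_img)) else NULL

  for (n in seq_len(n_img)) {
    zc <- matrix(fl$cls[, , n], ncell, nc)
    sig <- 1 / (1 + exp(-zc))
    zb <- array(fl$box[, , , n], c(ncell, reg_max, 4L))
    # decode distances and boxes
    E <- matrix(0, ncell, 4)
    P <- vector("list", 4)
    for (e in 1:4) {
      p <- softmax_rows(matrix(zb[, , e], ncell, reg_max))
      P[[e]] <- p
      E[, e] <- p %*% (0:(reg_max - 1))
    }
    D <- E * fl$stride
    pb <- cbind(fl$centers[, 1] - D[, 1], fl$centers[, 2] - D[, 2],
                fl$centers[, 1] + D[, 3], fl$centers[, 2] + D[, 4])
    g <- gt[[n]]
    gb <- if (is.null(g) || nrow(g) == 0) matrix(0, 0, 4) else
      as.matrix(g[, c("x1", "y1", "x2", "y2")])
    gcls <- if (nrow(gb)) as.integer(g$class_id) else integer(0)
    asg <- assign_targets(sig, pb, gb, gcls, fl$centers)
    ts <- asg$target_scores
    norm <- max(sum(ts), 1)

    bce <- pmax(zc, 0) - zc * ts + log1p(exp(-abs(zc)))
    cls_loss <- cls_loss + sum(sweep(bce, 2, cw, "*")) / norm
    if (with_grads) {
      dcls[, , n] <- sweep(sig - ts, 2, cw, "*") / norm
    }

    fg <- asg$fg_idx
    if (length(fg)) {
      wts <- rowSums(ts[fg, , drop = FALSE])
      tb <- asg$target_boxes
      # guard: predicted boxes can be degenerate early in training
      pbf <- pb[fg, , drop = FALSE]
      eps <- 1e-3
      pbf[, 3] <- pmax(pbf[, 3], pbf[, 1] + eps)
      pbf[, 4] <- pmax(pbf[, 4], pbf[, 2] + eps)
      cg <- ciou_with_grad(pbf, tb)
      box_loss <- box_loss + sum((1 - cg$ciou) * wts) / norm
      tdist <- target_ltrb(tb, fl$centers[fg, , drop = FALSE]) / fl$stride[fg]
      tdist <- pmin(pmax(tdist, 0), reg_max - 1 - 0.01)
      tl <- floor(tdist)
      wl <- tl + 1 - tdist
      wr <- tdist - tl
      for (e in 1:4) {
        pfe <- P[[e]][fg, , drop = FALSE]
        pl <- pfe[cbind(seq_along(fg), tl[, e] + 1)]
        pr <- pfe[cbind(seq_along(fg), pmin(tl[, e] + 2, reg_max))]
        ce <- -(wl[, e] * log(pmax(pl, 1e-12)) + wr[, e] * log(pmax(pr, 1e-12)))
        dfl_loss <- dfl_loss + sum(ce * wts) / (4 * norm)
        if (with_grads) {
          # DFL path: (p - two-point target) scaled
          tgt <- matrix(0, length(fg), reg_max)
          tgt[cbind(seq_along(fg), tl[, e] + 1)] <- wl[, e]
          iright <- pmin(tl[, e] + 2, reg_max)
          tgt[cbind(seq_along(fg), iright)] <- tgt[cbind(seq_along(fg), iright)] + wr[, e]
          gd <- (pfe - tgt) * (lw[["dfl"]] * wts / (4 * norm))
          # CIoU path: dL/dE_e via the softmax-expectation Jacobian
          sgn <- if (e <= 2) -1 else 1
          dl_dD <- -(lw[["box"]] * wts / norm) * cg$grad[, e] * sgn
          Ef <- E[fg, e]
          bins <- matrix(0:(reg_max - 1), length(fg), reg_max, byrow = TRUE)
          gb2 <- pfe * (bins - Ef) * (dl_dD * fl$stride[fg])
          tmp <- matrix(dbox[, , e, n], ncell, reg_max)
          tmp[fg, ] <- tmp[fg, ] + gd + gb2
          dbox[, , e, n] <- tmp
        }
      }
    }
  }
  if (with_grads) dcls <- dcls * lw[["cls"]]  # already weighted per class
  breakdown <- list(box_loss = box_loss / n_img, cls_loss = cls_loss / n_img,
                    dfl_loss = dfl_loss / n_img)
  breakdown$total <- lw[["box"]] * breakdown$box_loss +
    lw[["cls"]] * breakdown$cls_loss + lw[["dfl"]] * breakdown$dfl_loss
  out <- list(breakdown = breakdown)
  if (with_grads) {
    # batch-mean scaling and unflatten to per-level arrays
    dcls <- dcls / n_img
    dbox <- dbox / n_img
    grads <- list()
    off <- 0L
    for (lv in names(fl$sizes)) {
      d <- fl$sizes[[lv]]
      ncl <- d[1] * d[2]
      sel <- (off + 1L):(off + ncl)
      gc_ <- array(dcls[sel, , , drop = FALSE], c(d[1], d[2], nc, n_img))
      gbx <- array(dbox[sel, , , , drop = FALSE],
                   c(d[1], d[2], reg_max * 4L, n_img))
      grads[[lv]] <- list(cls = gc_, box = gbx)
      off <- off + ncl
    }
    out$grads <- grads
  }
  out
}
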