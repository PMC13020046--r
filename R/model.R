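#' Detector model configuration
#'
#' Describes a YOLOv8n-style single-stage anchor-free detector: a CSP-style
#' backbone (stem + four stages of stride-2 downsample + C2f), an SPPF block,
#' an FPN top-down / PAN bottom-up neck with two stride-2 downsample sites,
#' and a decoupled head predicting per-cell class logits and box-edge
#' distance distributions over `reg_max` bins at strides 8/16/32.
#'
#' `replacement_set` names the downsample sites realized as ADown blocks
#' (average pooling + channel split into a max-pool/1x1-conv branch and a
#' strided 3x3-conv branch) instead of plain 3x3 stride-2 convolutions.
#' Valid sites are `"P2","P3","P4","P5"` (backbone stages after the stem) and
#' `"N4","N5"` (the PAN downsamplers). The stem is never replaceable: ADown
#' needs an even channel split and the stem input is the image.
#'
#' @param num_classes number of object classes (3 for AO/OTA A1/A2/A3).
#' @param width_multiple,depth_multiple,max_channels nano-scale constants of
#'   the architecture family (0.25 / 0.33 / 1024).
#' @param reg_max number of discrete bins per box-edge distance.
#' @param input_channels image channels fed to the stem (grayscale images are
#'   replicated to 3 channels by the preprocessing step).
#' @param replacement_set character vector of downsample site ids to realize
#'   as ADown blocks; `character()` gives the plain baseline.
#' @return an object of class `fracdet_config`.
#' @export
model_config <- function(num_classes = 3,
                         width_multiple = 0.25,
                         depth_multiple = 0.33,
                         max_channels = 1024,
                         reg_max = 16,
                         input_channels = 3,
                         replacement_set = character()) {
  if (num_classes < 1) stop("num_classes must be >= 1")
  replacement_set <- as.character(replacement_set)
  valid <- c("P2", "P3", "P4", "P5", "N4", "N5")
  bad <- setdiff(replacement_set, valid)
  if (length(bad)) {
    stop("unknown downsample site(s) in replacement_set: ",
         paste(bad, collapse = ", "),
         " (the stem is never replaceable; valid sites: ",
         paste(valid, collapse = ", "), ")")
  }
  structure(list(num_classes = as.integer(num_classes),
                 width_multiple = width_multiple,
                 depth_multiple = depth_multiple,
                 max_channels = as.integer(max_channels),
                 reg_max = as.integer(reg_max),
                 input_channels = as.integer(input_channels),
                 replacement_set = sort(unique(replacement_set))),
            class = "fracdet_config")
}

#' Downsample sites calibrated against the published efficiency budget
#'
#' The shipped ADown variant replaces the four post-stem backbone
#' downsamplers and the deeper PAN downsampler. See
#' [calibrate_replacement_set()] for how this set is chosen.
#' @export
adown_default_sites <- function() c("P2", "P3", "P4", "P5", "N5")

make_divisible <- function(x, divisor = 8) {
  max(divisor, round(x / divisor) * divisor)
}

scaled_channels <- function(config) {
  base <- c(64, 128, 256, 512, 1024)
  vapply(base, function(b) {
    make_divisible(min(b, config$max_channels) * config$width_multiple)
  }, numeric(1))
}

scaled_depth <- function(n, config) max(round(n * config$depth_multiple), 1L)

# -- block builders over the graph builder ----------------------------------

bld_conv_block <- function(b, from, cin, cout, k, s, name) {
  b$conv(from, cin, cout, k = k, stride = s, name = name)
}

bld_adown <- function(b, from, cin, cout, name) {
  if (cin %% 2L != 0L || cout %% 2L != 0L) {
    stop("ADown requires even in/out channel counts, got ", cin, " -> ", cout)
  }
  h_in <- cin %/% 2L
  h_out <- cout %/% 2L
  ap <- b$avgpool2(from, name = name)
  g1 <- b$split(ap, 1L, h_in, name = name)
  g2 <- b$split(ap, h_in + 1L, cin, name = name)
  # first half: 3x3 s2 max pool then 1x1 fusion conv; second half: 3x3 s2 conv
  mp <- b$maxpool(g1, 3L, 2L, 1L, name = name)
  c1 <- b$conv(mp, h_in, h_out, k = 1L, stride = 1L, name = name)
  c2 <- b$conv(g2, h_in, h_out, k = 3L, stride = 2L, name = name)
  b$concat(c(c1, c2), name = name)
}

bld_downsample <- function(b, from, cin, cout, site, config, prefix) {
  name <- paste0(prefix, ".", site, ".down")
  if (site %in% config$replacement_set) {
    bld_adown(b, from, cin, cout, name)
  } else {
    bld_conv_block(b, from, cin, cout, 3L, 2L, name)
  }
}

bld_bottleneck <- function(b, from, c_, shortcut, name) {
  cv1 <- b$conv(from, c_, c_, k = 3L, stride = 1L, name = name)
  cv2 <- b$conv(cv1, c_, c_, k = 3L, stride = 1L, name = name)
  if (shortcut) b$add(from, cv2, name = name) else cv2
}

bld_c2f <- function(b, from, cin, cout, n, shortcut, name) {
  c_ <- cout %/% 2L
  cv1 <- b$conv(from, cin, 2L * c_, k = 1L, stride = 1L, name = name)
  y1 <- b$split(cv1, 1L, c_, name = name)
  y2 <- b$split(cv1, c_ + 1L, 2L * c_, name = name)
  ys <- c(y1, y2)
  cur <- y2
  for (i in seq_len(n)) {
    cur <- bld_bottleneck(b, cur, c_, shortcut, name)
    ys <- c(ys, cur)
  }
  cat <- b$concat(ys, name = name)
  b$conv(cat, (2L + n) * c_, cout, k = 1L, stride = 1L, name = name)
}

bld_sppf <- function(b, from, cin, cout, name) {
  c_ <- cin %/% 2L
  cv1 <- b$conv(from, cin, c_, k = 1L, stride = 1L, name = name)
  m1 <- b$maxpool(cv1, 5L, 1L, 2L, name = name)
  m2 <- b$maxpool(m1, 5L, 1L, 2L, name = name)
  m3 <- b$maxpool(m2, 5L, 1L, 2L, name = name)
  cat <- b$concat(c(cv1, m1, m2, m3), name = name)
  b$conv(cat, 4L * c_, cout, k = 1L, stride = 1L, name = name)
}

bld_head_branch <- function(b, from, cin, cmid, cfinal, name) {
  h1 <- b$conv(from, cin, cmid, k = 3L, stride = 1L, name = name)
  h2 <- b$conv(h1, cmid, cmid, k = 3L, stride = 1L, name = name)
  b$conv(h2, cmid, cfinal, k = 1L, stride = 1L,
         bn = FALSE, act = FALSE, bias = TRUE, name = name)
}

#' Assemble a detector
#'
#' Builds the full detector graph described by a [model_config()]: stem,
#' four backbone stages (downsample + C2f), SPPF, FPN/PAN neck, and the
#' decoupled anchor-free head. Each downsample site named in the config's
#' `replacement_set` is realized as an ADown block, the rest as plain 3x3
#' stride-2 convolution blocks. Weight initialization is He-style for conv
#' kernels and uses the family's customary head-bias priors; it is driven
#' entirely by the current RNG state, so `set.seed()` before calling makes
#' two builds identical.
#'
#' @param config a [model_config()].
#' @param init_weights if `FALSE`, parameters are left at zero (useful for
#'   pure accounting, which only needs shapes).
#' @return an object of class `fracdet_model`.
#' @export
assemble_model <- function(config = model_config(), init_weights = TRUE) {
  stopifnot(inherits(config, "fracdet_config"))
  ch <- scaled_channels(config)  # P1..P5 widths, e.g. 16 32 64 128 256
  nb <- vapply(c(3, 6, 6, 3), scaled_depth, integer(1) + 0, config = config)
  nn <- scaled_depth(3, config)
  b <- new_graph_builder()
  img <- b$input(config$input_channels)
  stem <- b$conv(img, config$input_channels, ch[1], k = 3L, stride = 2L,
                 name = "backbone.stem")

  d2 <- bld_downsample(b, stem, ch[1], ch[2], "P2", config, "backbone")
  s2 <- bld_c2f(b, d2, ch[2], ch[2], nb[1], TRUE, "backbone.P2.c2f")
  d3 <- bld_downsample(b, s2, ch[2], ch[3], "P3", config, "backbone")
  s3 <- bld_c2f(b, d3, ch[3], ch[3], nb[2], TRUE, "backbone.P3.c2f")
  d4 <- bld_downsample(b, s3, ch[3], ch[4], "P4", config, "backbone")
  s4 <- bld_c2f(b, d4, ch[4], ch[4], nb[3], TRUE, "backbone.P4.c2f")
  d5 <- bld_downsample(b, s4, ch[4], ch[5], "P5", config, "backbone")
  s5 <- bld_c2f(b, d5, ch[5], ch[5], nb[4], TRUE, "backbone.P5.c2f")
  sppf <- bld_sppf(b, s5, ch[5], ch[5], "backbone.sppf")

  up1 <- b$upsample2(sppf, name = "neck.up1")
  cat1 <- b$concat(c(up1, s4), name = "neck.cat1")
  n4td <- bld_c2f(b, cat1, ch[5] + ch[4], ch[4], nn, FALSE, "neck.P4.c2f")
  up2 <- b$upsample2(n4td, name = "neck.up2")
  cat2 <- b$concat(c(up2, s3), name = "neck.cat2")
  p3out <- bld_c2f(b, cat2, ch[4] + ch[3], ch[3], nn, FALSE, "neck.P3.c2f")
  dn4 <- bld_downsample(b, p3out, ch[3], ch[3], "N4", config, "neck")
  cat3 <- b$concat(c(dn4, n4td), name = "neck.cat3")
  p4out <- bld_c2f(b, cat3, ch[3] + ch[4], ch[4], nn, FALSE, "neck.N4.c2f")
  dn5 <- bld_downsample(b, p4out, ch[4], ch[4], "N5", config, "neck")
  cat4 <- b$concat(c(dn5, sppf), name = "neck.cat4")
  p5out <- bld_c2f(b, cat4, ch[4] + ch[5], ch[5], nn, FALSE, "neck.N5.c2f")

  nc <- config$num_classes
  rm4 <- 4L * config$reg_max
  cmid_box <- max(16L, ch[3] %/% 4L, rm4)
  cmid_cls <- max(ch[3], min(nc, 100L))
  levels <- list(p8 = list(node = p3out, cin = ch[3], stride = 8L),
                 p16 = list(node = p4out, cin = ch[4], stride = 16L),
                 p32 = list(node = p5out, cin = ch[5], stride = 32L))
  heads <- lapply(names(levels), function(lv) {
    L <- levels[[lv]]
    list(stride = L$stride,
         box = bld_head_branch(b, L$node, L$cin, cmid_box, rm4,
                               paste0("head.", lv, ".box")),
         cls = bld_head_branch(b, L$node, L$cin, cmid_cls, nc,
                               paste0("head.", lv, ".cls")))
  })
  names(heads) <- names(levels)

  model <- structure(list(config = config,
                          nodes = b$nodes,
                          params = b$params,
                          channels = b$channels,
                          heads = heads),
                     class = "fracdet_model")
  if (init_weights) model <- init_model_weights(model)
  model
}

init_model_weights <- function(model) {
  nodes <- model$nodes
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$kind != "conv") next
    fan_in <- nd$k^2 * nd$cin
    model$params[[i]]$w[] <- stats::rnorm(length(model$params[[i]]$w),
                                          sd = sqrt(2 / fan_in))
  }
  # head bias priors: box bias 1, class bias log-odds of a sparse prior
  for (lv in names(model$heads)) {
    h <- model$heads[[lv]]
    model$params[[h$box]]$b[] <- 1
    prior <- 5 / model$config$num_classes / (640 / h$stride)^2
    model$params[[h$cls]]$b[] <- log(prior / (1 - prior))
  }
  model
}

#' @export
print.fracdet_model <- function(x, ...) {
  cat(sprintf("<fracdet_model> %d classes, reg_max %d, %d graph nodes\n",
              x$config$num_classes, x$config$reg_max, length(x$nodes)))
  rs <- x$config$replacement_set
  cat("ADown sites:", if (length(rs)) paste(rs, collapse = " ") else "(none)", "\n")
  cat(sprintf("parameters: %s\n", format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Run the detector forward
#'
#' @param model a `fracdet_model`.
#' @param x image batch, array `(H, W, C, N)` with values in `[0, 1]`;
#'   `H` and `W` must be divisible by 32.
#' @param train if `TRUE`, batch-norm uses batch statistics.
#' @return a list with one element per pyramid level (`p8`, `p16`, `p32`),
#'   each holding `box` (`(h, w, 4*reg_max, N)` distance-distribution logits),
#'   `cls` (`(h, w, num_classes, N)` class logits) and `stride`.
#' @export
model_forward <- function(model, x, train = FALSE) {
  stopifnot(inherits(model, "fracdet_model"))
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    d <- dim(x)
  }
  if (length(d) != 4L) stop("input must be an (H, W, C, N) array")
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("input height/width must be divisible by 32, got ",
         d[1], "x", d[2])
  }
  if (d[3] != model$config$input_channels) {
    stop("input has ", d[3], " channels; model expects ",
         model$config$input_channels)
  }
  fw <- graph_forward(model, x, train = train, cache = FALSE)
  lapply(model$heads, function(h) {
    list(box = fw$acts[[h$box]], cls = fw$acts[[h$cls]], stride = h$stride)
  })
}

#' Decode raw predictions into scored boxes
#'
#' Box-edge distances are the expectation over the softmax of the `reg_max`
#' distribution bins, scaled by the level stride and offset from the cell
#' center; class scores are sigmoids. Detections above `conf_thresh` go
#' through greedy class-aware non-maximum suppression at `iou_thresh` and
#' are clipped to the image.
#'
#' @param raw output of [model_forward()].
#' @param conf_thresh,iou_thresh thresholds in `[0, 1]`.
#' @param image_id id attached to the returned records.
#' @param max_det keep at most this many detections.
#' @return a data.frame with columns
#'   `image_id, class_id, x1, y1, x2, y2, confidence`.
#' @export
postprocess <- function(raw, conf_thresh = 0.25, iou_thresh = 0.45,
                        image_id = 1L, max_det = 300L) {
  stopifnot(conf_thresh >= 0, conf_thresh <= 1, iou_thresh >= 0, iou_thresh <= 1)
  dec <- decode_predictions(raw)
  n_img <- dim(raw[[1]]$box)[4]
  out <- vector("list", n_img)
  for (n in seq_len(n_img)) {
    sc <- dec$scores[, , n]  # cells x classes
    if (is.null(dim(sc))) sc <- matrix(sc, ncol = 1)
    best <- max.col(sc, ties.method = "first")
    conf <- sc[cbind(seq_len(nrow(sc)), best)]
    keep <- which(conf >= conf_thresh)
    if (!length(keep)) {
      out[[n]] <- empty_detections()
      next
    }
    df <- data.frame(image_id = image_id[min(n, length(image_id))],
                     class_id = best[keep] - 1L,
                     x1 = dec$boxes[keep, 1, n], y1 = dec$boxes[keep, 2, n],
                     x2 = dec$boxes[keep, 3, n], y2 = dec$boxes[keep, 4, n],
                     confidence = conf[keep])
    df <- nms_classwise(df, iou_thresh)
    if (nrow(df) > max_det) df <- df[seq_len(max_det), ]
    # clip to image
    df$x1 <- pmin(pmax(df$x1, 0), dec$img_w)
    df$x2 <- pmin(pmax(df$x2, 0), dec$img_w)
    df$y1 <- pmin(pmax(df$y1, 0), dec$img_h)
    df$y2 <- pmin(pmax(df$y2, 0), dec$img_h)
    out[[n]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_detections <- function() {
  data.frame(image_id = integer(0), class_id = integer(0),
             x1 = numeric(0), y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
             confidence = numeric(0))
}

# Flatten all levels into per-cell decoded boxes (pixel xyxy) and class
# probabilities. Returns boxes (cells x 4 x N), scores (cells x nc x N).
decode_predictions <- function(raw) {
  reg_max <- dim(raw[[1]]$box)[3] %/% 4L
  n_img <- dim(raw[[1]]$box)[4]
  nc <- dim(raw[[1]]$cls)[3]
  boxes <- list()
  scores <- list()
  img_h <- dim(raw[[1]]$box)[1] * raw[[1]]$stride
  img_w <- dim(raw[[1]]$box)[2] * raw[[1]]$stride
  for (lv in raw) {
    d <- dim(lv$box)
    h <- d[1]; w <- d[2]
    ncell <- h * w
    # cell centers in pixels (row-major over (h, w) column-major array order)
    cy <- rep((seq_len(h) - 0.5) * lv$stride, times = w)
    cx <- rep((seq_len(w) - 0.5) * lv$stride, each = h)
    bm <- array(lv$box, c(ncell, reg_max, 4L, n_img))
    dist <- apply_dfl_expectation(bm, reg_max) * lv$stride  # ncell x 4 x N
    bx <- array(0, c(ncell, 4L, n_img))
    bx[, 1, ] <- cx - dist[, 1, ]
    bx[, 2, ] <- cy - dist[, 2, ]
    bx[, 3, ] <- cx + dist[, 3, ]
    bx[, 4, ] <- cy + dist[, 4, ]
    boxes[[length(boxes) + 1L]] <- bx
    sc <- array(lv$cls, c(ncell, nc, n_img))
    scores[[length(scores) + 1L]] <- 1 / (1 + exp(-sc))
  }
  bind1 <- function(lst) {
    tot <- sum(vapply(lst, function(a) dim(a)[1], integer(1)))
    out <- array(0, c(tot, dim(lst[[1]])[2], n_img))
    off <- 0L
    for (a in lst) {
      out[(off + 1L):(off + dim(a)[1]), , ] <- a
      off <- off + dim(a)[1]
    }
    out
  }
  list(boxes = bind1(boxes), scores = bind1(scores),
       img_h = img_h, img_w = img_w)
}

# bm: (ncell, reg_max, 4, N) logits -> expectation over softmax bins
apply_dfl_expectation <- function(bm, reg_max) {
  d <- dim(bm)
  # numerically stable softmax along the bin dimension
  mx <- apply(bm, c(1, 3, 4), max)
  e <- exp(bm - aperm(array(mx, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3)))
  s <- apply(e, c(1, 3, 4), sum)
  p <- e / aperm(array(s, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  bins <- array(rep(0:(reg_max - 1L), each = d[1]), c(d[1], d[2], d[3], d[4]))
  apply(p * bins, c(1, 3, 4), sum)
}

# Greedy class-aware NMS on a detection data.frame sorted by confidence.
# Candidates are capped at the top max_nms by confidence before suppression.
nms_classwise <- function(df, iou_thresh, max_nms = 1000L) {
  if (nrow(df) <= 1) return(df)
  ord <- order(-df$confidence)
  df <- df[ord, ]
  if (nrow(df) > max_nms) df <- df[seq_len(max_nms), ]
  x1 <- df$x1; y1 <- df$y1; x2 <- df$x2; y2 <- df$y2
  area <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  keep <- logical(nrow(df))
  for (cl in unique(df$class_id)) {
    idx <- which(df$class_id == cl)
    taken <- integer(0)
    for (i in idx) {
      ok <- TRUE
      if (length(taken)) {
        iw <- pmax(pmin(x2[i], x2[taken]) - pmax(x1[i], x1[taken]), 0)
        ih <- pmax(pmin(y2[i], y2[taken]) - pmax(y1[i], y1[taken]), 0)
        inter <- iw * ih
        iou <- inter / (area[i] + area[taken] - inter + 1e-12)
        ok <- all(iou <= iou_thresh)
      }
      if (ok) {
        keep[i] <- TRUE
        taken <- c(taken, i)
      }
    }
  }
  df <- df[keep, ]
  rownames(df) <- NULL
  df
}
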