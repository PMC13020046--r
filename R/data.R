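# Dataset I/O and preprocessing. Labels use the YOLO txt dialect: one
# "class cx cy w h" line per box, coordinates normalized to the unit square,
# class ids 0-based. Images are PNG; internally a grayscale image is a
# (H, W) matrix in [0, 1] and a model input is (H, W, 3) with the gray
# channel replicated.

#' Read / write YOLO-format label files
#'
#' @param path label file path.
#' @param num_classes valid class ids are `0 .. num_classes - 1`.
#' @return `read_yolo_labels`: data.frame with columns
#'   `class_id, cx, cy, w, h`. Malformed lines raise an error naming the
#'   line number.
#' @export
read_yolo_labels <- function(path, num_classes = 3) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                    w = numeric(0), h = numeric(0))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 5) {
      stop(sprintf("%s line %d: expected 5 fields, got %d", path, i, length(f)))
    }
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) stop(sprintf("%s line %d: non-numeric field", path, i))
    cls <- v[1]
    if (cls != round(cls) || cls < 0 || cls >= num_classes) {
      stop(sprintf("%s line %d: class id %s outside 0..%d", path, i, f[1],
                   num_classes - 1))
    }
    if (any(v[2:3] < 0 | v[2:3] > 1) || any(v[4:5] <= 0 | v[4:5] > 1)) {
      stop(sprintf("%s line %d: coordinates outside [0, 1]", path, i))
    }
    out <- rbind(out, data.frame(class_id = as.integer(cls), cx = v[2],
                                 cy = v[3], w = v[4], h = v[5]))
  }
  out
}

#' @rdname read_yolo_labels
#' @param labels data.frame with columns `class_id, cx, cy, w, h`.
#' @export
write_yolo_labels <- function(labels, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id, labels$cx,
                   labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' Load an image as a grayscale matrix
#'
#' Color images are reduced by the luminance weights
#' `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param path PNG file.
#' @return (H, W) matrix in `[0, 1]`.
#' @export
load_image_gray <- function(path) {
  img <- png::readPNG(path)
  to_gray(img)
}

to_gray <- function(img) {
  if (length(dim(img)) == 2) return(img)
  if (dim(img)[3] >= 3) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  img[, , 1]
}

LETTERBOX_FILL <- 114 / 255

#' Letterbox preprocessing
#'
#' Converts an image to luminance grayscale, resizes it preserving aspect
#' ratio to fit a square target, pads symmetrically with mid-gray, scales
#' to `[0, 1]` and replicates the gray channel to the model's 3 input
#' channels. The returned letterbox parameters allow exact box round-trips
#' via [boxes_to_input()] / [boxes_to_image()].
#'
#' @param image (H, W) or (H, W, 3) array in `[0, 1]`.
#' @param imgsz target side (divisible by 32).
#' @return list: `x` (imgsz, imgsz, 3), `scale`, `pad_x`, `pad_y`,
#'   `orig_hw`.
#' @export
preprocess <- function(image, imgsz = 640) {
  g <- to_gray(image)
  d <- dim(g)
  if (any(d == 0)) stop("empty image")
  scale <- min(imgsz / d[1], imgsz / d[2])
  nh <- round(d[1] * scale)
  nw <- round(d[2] * scale)
  r <- resize_bilinear(g, nh, nw)
  pad_y <- (imgsz - nh) %/% 2
  pad_x <- (imgsz - nw) %/% 2
  canvas <- matrix(LETTERBOX_FILL, imgsz, imgsz)
  canvas[pad_y + seq_len(nh), pad_x + seq_len(nw)] <- r
  x <- array(canvas, c(imgsz, imgsz, 3))
  list(x = x, scale = scale, pad_x = pad_x, pad_y = pad_y, orig_hw = d)
}

resize_bilinear <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  if (nh == h && nw == w) return(m)
  ys <- (seq_len(nh) - 0.5) * h / nh - 0.5
  xs <- (seq_len(nw) - 0.5) * w / nw - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- m[y1 + 1, x0 + 1, drop = FALSE]; d_ <- m[y1 + 1, x1 + 1, drop = FALSE]
  top <- a * outer(rep(1, nh), 1 - wx) + b * outer(rep(1, nh), wx)
  bot <- c_ * outer(rep(1, nh), 1 - wx) + d_ * outer(rep(1, nh), wx)
  top * outer(1 - wy, rep(1, nw)) + bot * outer(wy, rep(1, nw))
}

#' Map normalized labels to letterboxed input pixels (and back)
#'
#' @param labels data.frame `class_id, cx, cy, w, h` (normalized to the
#'   original image).
#' @param lb letterbox parameters from [preprocess()].
#' @return `boxes_to_input`: data.frame `class_id, x1, y1, x2, y2` in input
#'   pixels; `boxes_to_image` inverts it back to normalized labels.
#' @export
boxes_to_input <- function(labels, lb) {
  oh <- lb$orig_hw[1]; ow <- lb$orig_hw[2]
  cx <- labels$cx * ow * lb$scale + lb$pad_x
  cy <- labels$cy * oh * lb$scale + lb$pad_y
  w <- labels$w * ow * lb$scale
  h <- labels$h * oh * lb$scale
  data.frame(class_id = labels$class_id,
             x1 = cx - w / 2, y1 = cy - h / 2,
             x2 = cx + w / 2, y2 = cy + h / 2)
}

#' @rdname boxes_to_input
#' @param boxes data.frame `class_id, x1, y1, x2, y2` in input pixels.
#' @export
boxes_to_image <- function(boxes, lb) {
  oh <- lb$orig_hw[1]; ow <- lb$orig_hw[2]
  cx <- ((boxes$x1 + boxes$x2) / 2 - lb$pad_x) / lb$scale / ow
  cy <- ((boxes$y1 + boxes$y2) / 2 - lb$pad_y) / lb$scale / oh
  w <- (boxes$x2 - boxes$x1) / lb$scale / ow
  h <- (boxes$y2 - boxes$y1) / lb$scale / oh
  data.frame(class_id = boxes$class_id, cx = cx, cy = cy, w = w, h = h)
}

#' Seeded random train/test split
#'
#' Shuffles ids with the given seed and takes `floor(fraction * n)` for
#' training — the convention under which 976 ids at 8:2 leave 196 for test
#' and 1,952 at 7:3 leave 586 for validation.
#'
#' @param ids vector of ids (n >= 2).
#' @param train_fraction in (0, 1).
#' @param seed integer seed.
#' @param stratify_by optional factor (same length) for per-stratum splits.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_dataset <- function(ids, train_fraction = 0.8, seed = 0,
                          stratify_by = NULL) {
  n <- length(ids)
  if (n < 2) stop("need at least 2 ids to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (!is.null(stratify_by)) {
    stopifnot(length(stratify_by) == n)
    tr <- c(); te <- c()
    for (lev in unique(stratify_by)) {
      sub <- split_dataset(ids[stratify_by == lev], train_fraction,
                           seed = seed + match(lev, unique(stratify_by)))
      tr <- c(tr, sub$train); te <- c(te, sub$test)
    }
    return(list(train = tr, test = te))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(n)
  k <- floor(train_fraction * n)
  list(train = ids[perm[seq_len(k)]], test = ids[perm[(k + 1):n]])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Horizontal flip of an image and its labels
#'
#' Mirrors the image left-right and maps each label center `cx -> 1 - cx`;
#' classes and box sizes are unchanged. An involution.
#'
#' @param image (H, W) matrix or (H, W, C) array.
#' @param labels data.frame `class_id, cx, cy, w, h`.
#' @return list `(image, labels)`.
#' @export
hflip <- function(image, labels) {
  if (length(dim(image)) == 2) {
    image <- image[, rev(seq_len(ncol(image)))]
  } else {
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  }
  labels$cx <- 1 - labels$cx
  list(image = image, labels = labels)
}

#' Augmentation configuration
#'
#' @param hsv_h,hsv_s,hsv_v hue/saturation/value jitter gains. On grayscale
#'   inputs hue and saturation are no-ops; value jitter remains effective.
#' @param translate max fractional translation.
#' @param scale fractional scale jitter (factor in `[1 - scale, 1 + scale]`).
#' @param fliplr horizontal-flip probability.
#' @param mosaic mosaic probability.
#' @return a `fracdet_augment_config`.
#' @export
augment_config <- function(hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4,
                           translate = 0.1, scale = 0.5, fliplr = 0.5,
                           mosaic = 1.0) {
  stopifnot(fliplr >= 0, fliplr <= 1, mosaic >= 0, mosaic <= 1,
            hsv_h >= 0, hsv_s >= 0, hsv_v >= 0)
  structure(list(hsv_h = hsv_h, hsv_s = hsv_s, hsv_v = hsv_v,
                 translate = translate, scale = scale, fliplr = fliplr,
                 mosaic = mosaic),
            class = "fracdet_augment_config")
}

# HSV jitter with random gains; grayscale images (equal channels) keep
# hue/saturation degenerate so only the value gain has an effect.
hsv_jitter <- function(image, cfg) {
  gains <- 1 + stats::runif(3, -1, 1) * c(cfg$hsv_h, cfg$hsv_s, cfg$hsv_v)
  if (length(dim(image)) == 2) {
    return(pmin(pmax(image * gains[3], 0), 1))
  }
  d <- dim(image)
  rgb <- matrix(image, ncol = 3)
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
  h <- (hsv[1, ] * gains[1]) %% 1
  s <- pmin(pmax(hsv[2, ] * gains[2], 0), 1)
  v <- pmin(pmax(hsv[3, ] * gains[3], 0), 1)
  # vectorized HSV -> RGB
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t_ <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t_, v)))))
  g <- ifelse(i == 0, t_, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t_,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(cbind(r, g, b), d)
}

#' Mosaic composition with random affine
#'
#' Places four images on a 2x2 canvas around a jittered center, remaps their
#' labels to canvas coordinates, applies a random scale/translate affine and
#' crops back to the working size. Boxes are clipped to the output; boxes
#' shrunk below 2 px are dropped. HSV (value, for grayscale) jitter is
#' applied last.
#'
#' @param images list of 4 (s, s) grayscale matrices.
#' @param labels list of 4 label data.frames (normalized).
#' @param cfg an [augment_config()].
#' @return list `(image, labels)` with a (s, s) image and normalized labels.
#' @export
mosaic_and_affine <- function(images, labels, cfg = augment_config()) {
  stopifnot(length(images) == 4, length(labels) == 4)
  s <- nrow(images[[1]])
  canvas <- matrix(LETTERBOX_FILL, 2 * s, 2 * s)
  xc <- round(stats::runif(1, 0.5 * s, 1.5 * s))
  yc <- round(stats::runif(1, 0.5 * s, 1.5 * s))
  all_boxes <- list()
  for (k in 1:4) {
    img <- images[[k]]
    # quadrant k top-left corner on the canvas
    ox <- if (k %% 2 == 1) xc - s else xc
    oy <- if (k <= 2) yc - s else yc
    rx <- max(1, ox + 1):min(2 * s, ox + s)
    ry <- max(1, oy + 1):min(2 * s, oy + s)
    canvas[ry, rx] <- img[ry - oy, rx - ox]
    lb <- labels[[k]]
    if (nrow(lb)) {
      all_boxes[[k]] <- data.frame(
        class_id = lb$class_id,
        x1 = lb$cx * s - lb$w * s / 2 + ox, y1 = lb$cy * s - lb$h * s / 2 + oy,
        x2 = lb$cx * s + lb$w * s / 2 + ox, y2 = lb$cy * s + lb$h * s / 2 + oy)
    }
  }
  boxes <- do.call(rbind, all_boxes)
  # random affine: scale then translate, output window of size s centered
  sc <- stats::runif(1, 1 - cfg$scale, 1 + cfg$scale)
  tx <- stats::runif(1, 0.5 - cfg$translate, 0.5 + cfg$translate) * s
  ty <- stats::runif(1, 0.5 - cfg$translate, 0.5 + cfg$translate) * s
  # output pixel (i, j) samples canvas at the affine preimage
  ys <- ((seq_len(s) - ty) / sc) + s
  xs <- ((seq_len(s) - tx) / sc) + s
  yi <- round(ys); xi <- round(xs)
  ok_y <- yi >= 1 & yi <= 2 * s
  ok_x <- xi >= 1 & xi <= 2 * s
  out <- matrix(LETTERBOX_FILL, s, s)
  out[ok_y, ok_x] <- canvas[yi[ok_y], xi[ok_x]]
  out_labels <- data.frame(class_id = integer(0), cx = numeric(0),
                           cy = numeric(0), w = numeric(0), h = numeric(0))
  if (!is.null(boxes) && nrow(boxes)) {
    # same affine on boxes: canvas coord c -> (c - s) * sc + t
    bx1 <- (boxes$x1 - s) * sc + tx; bx2 <- (boxes$x2 - s) * sc + tx
    by1 <- (boxes$y1 - s) * sc + ty; by2 <- (boxes$y2 - s) * sc + ty
    bx1 <- pmin(pmax(bx1, 0), s); bx2 <- pmin(pmax(bx2, 0), s)
    by1 <- pmin(pmax(by1, 0), s); by2 <- pmin(pmax(by2, 0), s)
    keep <- (bx2 - bx1) >= 2 & (by2 - by1) >= 2
    if (any(keep)) {
      out_labels <- data.frame(class_id = boxes$class_id[keep],
                               cx = (bx1[keep] + bx2[keep]) / 2 / s,
                               cy = (by1[keep] + by2[keep]) / 2 / s,
                               w = (bx2[keep] - bx1[keep]) / s,
                               h = (by2[keep] - by1[keep]) / s)
    }
  }
  out <- hsv_jitter(out, cfg)
  list(image = out, labels = out_labels)
}

#' Label-set statistics
#'
#' Per-class instance counts, 2-d histograms of box centers and sizes, the
#' aspect-ratio histogram and pairwise correlations among
#' `(cx, cy, w, h)` — the usual label-distribution diagnostics.
#'
#' @param labels a data.frame of labels (`class_id, cx, cy, w, h`), or a
#'   manifest from [dataset_manifest()] whose label files are then read.
#' @param nbins histogram resolution.
#' @param num_classes number of classes.
#' @return list: `counts`, `center_hist`, `size_hist`, `aspect_hist`,
#'   `correlations` (4 x 4), `constant_attrs` (flag for zero-variance
#'   attributes, whose correlations are reported as 0).
#' @export
label_stats <- function(labels, nbins = 20, num_classes = 3) {
  if (inherits(labels, "fracdet_manifest")) {
    labels <- do.call(rbind, lapply(labels$label_paths, read_yolo_labels,
                                    num_classes = num_classes))
  }
  if (is.null(labels) || nrow(labels) == 0) stop("no labels to summarize")
  counts <- tabulate(labels$class_id + 1, nbins = num_classes)
  brk <- seq(0, 1, length.out = nbins + 1)
  cut2 <- function(a, b) {
    table(cut(a, brk, include.lowest = TRUE), cut(b, brk, include.lowest = TRUE))
  }
  m <- as.matrix(labels[, c("cx", "cy", "w", "h")])
  sds <- apply(m, 2, stats::sd)
  const <- sds < 1e-12 | is.na(sds)
  cors <- matrix(0, 4, 4, dimnames = list(colnames(m), colnames(m)))
  diag(cors) <- 1
  ok <- which(!const)
  if (length(ok) >= 2) {
    cors[ok, ok] <- stats::cor(m[, ok, drop = FALSE])
  }
  aspect <- labels$h / labels$w
  list(counts = counts,
       center_hist = cut2(labels$cx, labels$cy),
       size_hist = cut2(labels$w, labels$h),
       aspect_hist = graphics::hist(aspect, breaks = 20, plot = FALSE),
       correlations = cors,
       constant_attrs = const)
}

#' Dataset manifest
#'
#' Describes a dataset in the YOLO directory dialect
#' (`images/{train,val}/*.png`, `labels/{train,val}/*.txt`, `data.yaml`).
#'
#' @param dir dataset root containing `data.yaml`.
#' @return a `fracdet_manifest`: `image_paths`, `label_paths`, `class_names`,
#'   `counts` (per-class instances), `split` (train/val per item), `dir`.
#' @export
dataset_manifest <- function(dir) {
  yml <- file.path(dir, "data.yaml")
  if (!file.exists(yml)) stop("no data.yaml under ", dir)
  meta <- yaml::read_yaml(yml)
  image_paths <- character(0); label_paths <- character(0); split <- character(0)
  for (sp in c("train", "val")) {
    imgs <- sort(list.files(file.path(dir, "images", sp), pattern = "\\.png$",
                            full.names = TRUE))
    for (im in imgs) {
      lab <- file.path(dir, "labels", sp,
                       sub("\\.png$", ".txt", basename(im)))
      if (!file.exists(lab)) stop("missing label file for ", im)
      image_paths <- c(image_paths, im)
      label_paths <- c(label_paths, lab)
      split <- c(split, sp)
    }
  }
  nc <- length(meta$names)
  counts <- integer(nc)
  for (lp in label_paths) {
    lb <- read_yolo_labels(lp, num_classes = nc)
    counts <- counts + tabulate(lb$class_id + 1, nbins = nc)
  }
  structure(list(image_paths = image_paths, label_paths = label_paths,
                 class_names = unlist(meta$names), counts = counts,
                 split = split, dir = dir),
            class = "fracdet_manifest")
}

#' Convert a Labelme-style rectangle annotation to YOLO labels
#'
#' Reads the JSON produced by rectangle annotation (fields `shapes[].label`,
#' `shapes[].points`, `imageHeight`, `imageWidth`) and converts to
#' normalized center format.
#'
#' @param json_path annotation file.
#' @param class_names label-name to class-id mapping (position = id + 1).
#' @return label data.frame.
#' @export
labelme_to_yolo <- function(json_path, class_names = c("A1", "A2", "A3")) {
  j <- jsonlite::read_json(json_path)
  h <- j$imageHeight; w <- j$imageWidth
  rows <- lapply(j$shapes, function(s) {
    cls <- match(s$label, class_names) - 1L
    if (is.na(cls)) stop("unknown label: ", s$label)
    pts <- do.call(rbind, lapply(s$points, unlist))
    x1 <- min(pts[, 1]); x2 <- max(pts[, 1])
    y1 <- min(pts[, 2]); y2 <- max(pts[, 2])
    data.frame(class_id = cls, cx = (x1 + x2) / 2 / w, cy = (y1 + y2) / 2 / h,
               w = (x2 - x1) / w, h = (y2 - y1) / h)
  })
  do.call(rbind, rows)
}
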