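# Seeded synthetic femur-radiograph phantoms. Each image carries a bright
# bone silhouette (shaft, femoral head, trochanteric bulge) on a darker
# background, with a class-specific fracture pattern carved as dark line
# segments through the trochanteric region:
#   class 0 (A1-like): one oblique line,
#   class 1 (A2-like): two to three intersecting lines (multifragmentary),
#   class 2 (A3-like): one transverse / reverse-oblique line below the
#     trochanter.
# The contract is statistical structure (small single target, three
# separable pattern classes, configurable class imbalance), not radiological
# realism.

#' Phantom generator configuration
#'
#' Defaults emulate the make-up of the clinical set the generator stands in
#' for: three classes with imbalanced mix 261/579/136 and one annotated
#' fracture box per image.
#'
#' @param imgsz image side in pixels (divisible by 32).
#' @param class_mix per-class proportions (normalized internally).
#' @param bone_intensity range of the bone plateau gray level.
#' @param background background gray level.
#' @param blur_sigma Gaussian blur, pixels (scaled with `imgsz / 640`).
#' @param noise_sigma additive Gaussian noise sd.
#' @param fracture_contrast fractional darkening along carved lines.
#' @param line_width_frac fracture line width range, fraction of `imgsz`.
#' @param seed dataset-level seed.
#' @return a `fracdet_phantom_config`.
#' @export
phantom_config <- function(imgsz = 640,
                           class_mix = c(261, 579, 136) / 976,
                           bone_intensity = c(0.65, 0.85),
                           background = 0.22,
                           blur_sigma = 1.5,
                           noise_sigma = 0.03,
                           fracture_contrast = 0.45,
                           line_width_frac = c(0.008, 0.016),
                           seed = 0) {
  if (imgsz %% 32 != 0) stop("imgsz must be divisible by 32")
  if (any(class_mix < 0) || sum(class_mix) <= 0) stop("invalid class mix")
  if (blur_sigma < 0 || noise_sigma < 0) stop("sigmas must be >= 0")
  structure(list(imgsz = as.integer(imgsz),
                 class_mix = class_mix / sum(class_mix),
                 bone_intensity = bone_intensity, background = background,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 fracture_contrast = fracture_contrast,
                 line_width_frac = line_width_frac,
                 seed = as.integer(seed)),
            class = "fracdet_phantom_config")
}

# mask of pixels within halfw of segment (x0,y0)-(x1,y1); coords in pixels
seg_mask <- function(H, W, x0, y0, x1, y1, halfw) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  t <- ((xs - x0) * dx + (ys - y0) * dy) / max(len2, 1e-9)
  t <- pmin(pmax(t, 0), 1)
  px <- x0 + t * dx; py <- y0 + t * dy
  (xs - px)^2 + (ys - py)^2 <= halfw^2
}

disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, H, W)
  for (o in -r:r) out <- out + k[o + r + 1] * m[pad(seq_len(H) + o, H), ]
  m2 <- out
  out <- matrix(0, H, W)
  for (o in -r:r) out <- out + k[o + r + 1] * m2[, pad(seq_len(W) + o, W)]
  out
}

# class-specific fracture geometry; returns list of segments (pixel coords)
sample_fracture_pattern <- function(class_id, s, shaft_x, troch_y) {
  deg <- pi / 180
  seg_at <- function(cx, cy, angle, len) {
    c(cx - cos(angle) * len / 2, cy - sin(angle) * len / 2,
      cx + cos(angle) * len / 2, cy + sin(angle) * len / 2)
  }
  if (class_id == 0L) {
    # single oblique line through the trochanteric region
    ang <- stats::runif(1, 30, 60) * deg
    len <- stats::runif(1, 0.16, 0.24) * s
    cx <- shaft_x + stats::runif(1, -0.02, 0.02) * s
    cy <- troch_y + stats::runif(1, -0.02, 0.04) * s
    segs <- list(seg_at(cx, cy, ang, len))
  } else if (class_id == 1L) {
    # primary oblique plus 1-2 crossing lines with a fragment offset
    n_extra <- sample(1:2, 1)
    ang <- stats::runif(1, 30, 60) * deg
    len <- stats::runif(1, 0.18, 0.26) * s
    cx <- shaft_x + stats::runif(1, -0.02, 0.02) * s
    cy <- troch_y + stats::runif(1, -0.02, 0.04) * s
    segs <- list(seg_at(cx, cy, ang, len))
    for (k in seq_len(n_extra)) {
      a2 <- ang + stats::runif(1, 50, 110) * deg
      off <- stats::runif(2, -0.03, 0.03) * s
      segs <- c(segs, list(seg_at(cx + off[1], cy + off[2], a2,
                                  stats::runif(1, 0.12, 0.2) * s)))
    }
  } else if (class_id == 2L) {
    # transverse / reverse-oblique line below the trochanter
    ang <- sample(c(-1, 1), 1) * stats::runif(1, 0, 20) * deg
    len <- stats::runif(1, 0.18, 0.26) * s
    cx <- shaft_x + stats::runif(1, -0.02, 0.02) * s
    cy <- troch_y + stats::runif(1, 0.10, 0.16) * s
    segs <- list(seg_at(cx, cy, ang, len))
  } else {
    stop("class_id must be 0, 1 or 2")
  }
  list(kind = c("A1", "A2", "A3")[class_id + 1], n_lines = length(segs),
       segments = segs)
}

#' Generate one phantom radiograph
#'
#' Renders a femur phantom, carves the class's fracture pattern, applies
#' blur and noise, and returns the image with its tight fracture box (5%
#' margin). Deterministic given the current RNG state.
#'
#' @param config a [phantom_config()].
#' @param class_id 0 (A1-like), 1 (A2-like) or 2 (A3-like).
#' @return list: `image` (imgsz x imgsz matrix in `[0, 1]`), `label`
#'   (one-row data.frame `class_id, cx, cy, w, h`), `pattern` (fracture
#'   geometry record: `kind`, `n_lines`, `segments`), `signal` (measured
#'   fracture contrast on the final image: `carved_mean`, `bone_mean`,
#'   `contrast`).
#' @export
generate_example <- function(config, class_id) {
  if (!class_id %in% 0:2) stop("class_id must be 0, 1 or 2")
  s <- config$imgsz
  bone <- stats::runif(1, config$bone_intensity[1], config$bone_intensity[2])
  img <- matrix(config$background, s, s)

  shaft_x <- stats::runif(1, 0.42, 0.55) * s
  shaft_w <- stats::runif(1, 0.14, 0.2) * s
  troch_y <- stats::runif(1, 0.3, 0.38) * s
  head_r <- stats::runif(1, 0.07, 0.1) * s
  side <- sample(c(-1, 1), 1)
  head_x <- shaft_x + side * (shaft_w / 2 + head_r * 1.1)
  head_y <- troch_y - stats::runif(1, 0.08, 0.12) * s

  shaft <- seg_mask(s, s, shaft_x, troch_y - 0.05 * s, shaft_x, s, shaft_w / 2)
  bulge <- disk_mask(s, s, shaft_x, troch_y, shaft_w * 0.75)
  head <- disk_mask(s, s, head_x, head_y, head_r)
  neck <- seg_mask(s, s, head_x, head_y, shaft_x, troch_y, head_r * 0.7)
  bone_mask <- shaft | bulge | head | neck
  img[bone_mask] <- bone

  pat <- sample_fracture_pattern(class_id, s, shaft_x, troch_y)
  halfw <- stats::runif(1, config$line_width_frac[1],
                        config$line_width_frac[2]) * s / 2
  halfw <- max(halfw, 0.75)
  carved <- matrix(FALSE, s, s)
  for (sg in pat$segments) {
    carved <- carved | (seg_mask(s, s, sg[1], sg[2], sg[3], sg[4], halfw) &
                          bone_mask)
  }
  img[carved] <- bone * (1 - config$fracture_contrast)

  idx <- which(carved, arr.ind = TRUE)
  if (!nrow(idx)) {
    # pattern missed the bone (extreme geometry draw): carve at the bulge
    fb <- seg_mask(s, s, shaft_x - 0.08 * s, troch_y, shaft_x + 0.08 * s,
                   troch_y + 0.05 * s, halfw)
    carved <- fb & bone_mask
    if (!any(carved)) carved <- fb
    img[carved] <- bone * (1 - config$fracture_contrast)
    idx <- which(carved, arr.ind = TRUE)
  }
  y1 <- min(idx[, 1]); y2 <- max(idx[, 1])
  x1 <- min(idx[, 2]); x2 <- max(idx[, 2])
  mx <- 0.05 * (x2 - x1 + 1); my <- 0.05 * (y2 - y1 + 1)
  x1 <- max(x1 - mx, 0); x2 <- min(x2 + mx, s)
  y1 <- max(y1 - my, 0); y2 <- min(y2 + my, s)

  img <- gauss_blur(img, config$blur_sigma * s / 640)
  if (config$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(s * s, sd = config$noise_sigma), s, s)
  }
  img <- pmin(pmax(img, 0), 1)

  # measured fracture signal on the final image: carved pixels vs intact bone
  intact <- bone_mask & !carved
  signal <- list(carved_mean = mean(img[carved]),
                 bone_mean = mean(img[intact]),
                 contrast = mean(img[intact]) - mean(img[carved]))

  label <- data.frame(class_id = as.integer(class_id),
                      cx = (x1 + x2) / 2 / s, cy = (y1 + y2) / 2 / s,
                      w = min((x2 - x1) / s, 1), h = min((y2 - y1) / s, 1))
  list(image = img, label = label, pattern = pat, signal = signal)
}

#' Largest-remainder apportionment of class counts
#'
#' Deterministically apportions `n` items to the mix proportions: floor of
#' each quota, remaining items to the largest fractional remainders, ties
#' broken in class order. The defaults thus reproduce a 261/579/136 split
#' at `n = 976` exactly rather than in expectation.
#'
#' @param n total count.
#' @param mix proportions (normalized internally).
#' @return integer vector summing to `n`.
#' @export
apportion_counts <- function(n, mix) {
  mix <- mix / sum(mix)
  quota <- n * mix
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a phantom dataset on disk
#'
#' Writes the YOLO directory dialect (`images/{train,val}`,
#' `labels/{train,val}`, `data.yaml`). Class counts follow deterministic
#' largest-remainder apportionment of the configured mix; the train/val
#' assignment is a seeded shuffle at `1 - val_fraction`. Fully reproducible
#' from `config$seed`.
#'
#' @param n number of images.
#' @param config a [phantom_config()].
#' @param out_dir output directory (created).
#' @param val_fraction fraction of images assigned to the val split.
#' @return the [dataset_manifest()] of the written dataset.
#' @export
generate_dataset <- function(n, config = phantom_config(), out_dir,
                             val_fraction = 0.2) {
  if (n < 1) stop("n must be >= 1")
  counts <- apportion_counts(n, config$class_mix)
  classes <- rep(seq_along(counts) - 1L, counts)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  classes <- classes[sample(n)]
  split <- rep("train", n)
  if (val_fraction > 0 && n >= 2) {
    sp <- split_dataset(seq_len(n), 1 - val_fraction, seed = config$seed)
    split[sp$test] <- "val"
  }
  for (d in c("images/train", "images/val", "labels/train", "labels/val")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(n)) {
    ex <- generate_example(config, classes[i])
    base <- sprintf("phantom_%04d", i)
    png::writePNG(ex$image, file.path(out_dir, "images", split[i],
                                      paste0(base, ".png")))
    write_yolo_labels(ex$label, file.path(out_dir, "labels", split[i],
                                          paste0(base, ".txt")))
  }
  yaml::write_yaml(list(names = list("A1", "A2", "A3"), nc = 3,
                        train = "images/train", val = "images/val"),
                   file.path(out_dir, "data.yaml"))
  dataset_manifest(out_dir)
}
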