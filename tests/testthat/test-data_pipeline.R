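# Label I/O, letterboxing, splitting, augmentation, label analytics.

test_that("YOLO label files round-trip and reject malformed lines", {
  f <- tempfile(fileext = ".txt")
  writeLines("1 0.5 0.5 0.2 0.3", f)
  lb <- read_yolo_labels(f)
  expect_equal(lb$class_id, 1L)
  expect_equal(unlist(lb[1, 2:5], use.names = FALSE), c(0.5, 0.5, 0.2, 0.3))
  set.seed(51)
  many <- data.frame(class_id = sample(0:2, 100, TRUE),
                     cx = round(runif(100), 6), cy = round(runif(100), 6),
                     w = round(runif(100, 0.01, 1), 6),
                     h = round(runif(100, 0.01, 1), 6))
  write_yolo_labels(many, f)
  expect_equal(read_yolo_labels(f), many)
  writeLines("3 0.5 0.5 0.2 0.3", f)
  expect_error(read_yolo_labels(f), "line 1.*class id")
  writeLines(c("1 0.5 0.5 0.2 0.3", "0 1.5 0.5 0.2 0.3"), f)
  expect_error(read_yolo_labels(f), "line 2")
  writeLines("0 0.5 0.5 0.2", f)
  expect_error(read_yolo_labels(f), "5 fields")
})

test_that("letterboxing preserves aspect and inverts exactly on boxes", {
  img <- matrix(runif(640 * 1280), 640, 1280)  # 1280 wide, 640 tall
  lb <- preprocess(img, imgsz = 640)
  expect_equal(dim(lb$x), c(640, 640, 3))
  expect_equal(lb$scale, 0.5)
  expect_equal(lb$pad_y, 160)
  expect_equal(lb$pad_x, 0)
  # already-at-size grayscale is unchanged (identity letterbox)
  sq <- matrix(runif(96 * 96), 96, 96)
  lb2 <- preprocess(sq, imgsz = 96)
  expect_equal(lb2$x[, , 1], sq)
  expect_equal(lb2$x[, , 2], sq)
  # inverse contract on random boxes
  set.seed(52)
  labs <- data.frame(class_id = sample(0:2, 100, TRUE),
                     cx = runif(100, 0.2, 0.8), cy = runif(100, 0.2, 0.8),
                     w = runif(100, 0.05, 0.3), h = runif(100, 0.05, 0.3))
  back <- boxes_to_image(boxes_to_input(labs, lb), lb)
  expect_equal(back, labs, tolerance = 1e-12)
})

test_that("split sizes reproduce the published train/test counts", {
  sp <- split_dataset(seq_len(976), 0.8, seed = 1)
  expect_length(sp$train, 780)
  expect_length(sp$test, 196)
  sp2 <- split_dataset(seq_len(1952), 0.7, seed = 1)
  expect_length(sp2$train, 1366)
  expect_length(sp2$test, 586)
  expect_identical(split_dataset(1:50, 0.8, seed = 9),
                   split_dataset(1:50, 0.8, seed = 9))
  expect_error(split_dataset(1, 0.8, 1), "at least 2")
  expect_error(split_dataset(1:10, 1.2, 1), "train_fraction")
})

test_that("splits partition the ids for random sizes and seeds", {
  set.seed(53)
  for (trial in 1:25) {
    n <- sample(2:500, 1)
    frac <- runif(1, 0.1, 0.9)
    sp <- split_dataset(seq_len(n), frac, seed = sample(1e6, 1))
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_len(n))
    expect_length(sp$train, floor(frac * n))
  }
})

test_that("horizontal flip is an involution that mirrors centers", {
  img <- matrix(runif(64 * 64), 64, 64)
  labs <- data.frame(class_id = c(0L, 1L, 2L), cx = c(0.3, 0.5, 0.9),
                     cy = c(0.2, 0.5, 0.7), w = rep(0.1, 3), h = rep(0.1, 3))
  fl <- hflip(img, labs)
  expect_equal(fl$labels$cx, c(0.7, 0.5, 0.1))
  expect_equal(fl$labels$cy, labs$cy)
  expect_equal(fl$labels$class_id, labs$class_id)
  back <- hflip(fl$image, fl$labels)
  expect_equal(back$image, img)
  expect_equal(back$labels, labs)
})

test_that("flip doubling doubles per-class instance counts", {
  items <- make_phantom_items(9, imgsz = 96, seed = 54)
  labs <- do.call(rbind, lapply(items, `[[`, "labels"))
  doubled <- rbind(labs, do.call(rbind, lapply(items, function(it) {
    hflip(it$image, it$labels)$labels
  })))
  expect_equal(tabulate(doubled$class_id + 1, 3),
               2 * tabulate(labs$class_id + 1, 3))
})

test_that("mosaic keeps labels valid, is seeded, and clips off-canvas boxes", {
  items <- make_phantom_items(4, imgsz = 96, seed = 55)
  cfg <- augment_config()
  run <- function(seed) {
    set.seed(seed)
    mosaic_and_affine(lapply(items, `[[`, "image"),
                      lapply(items, `[[`, "labels"), cfg)
  }
  m1 <- run(3)
  m2 <- run(3)
  expect_identical(m1, m2)
  expect_equal(dim(m1$image), c(96, 96))
  if (nrow(m1$labels)) {
    expect_true(all(m1$labels$w > 0 & m1$labels$h > 0))
    expect_true(all(m1$labels$cx - m1$labels$w / 2 >= -1e-9))
    expect_true(all(m1$labels$cx + m1$labels$w / 2 <= 1 + 1e-9))
    expect_true(all(m1$labels$cy + m1$labels$h / 2 <= 1 + 1e-9))
  }
  # boxes translated far off-canvas vanish
  far <- lapply(items, function(it) {
    it$labels$cx <- it$labels$cx * 0 + 1e-6
    it$labels$cy <- it$labels$cy * 0 + 1e-6
    it$labels$w <- it$labels$w * 0 + 1e-6
    it$labels$h <- it$labels$h * 0 + 1e-6
    it$labels
  })
  set.seed(4)
  m3 <- mosaic_and_affine(lapply(items, `[[`, "image"), far, cfg)
  expect_equal(nrow(m3$labels), 0)
})

test_that("HSV jitter on grayscale degenerates to a value gain", {
  img <- matrix(runif(32 * 32, 0.2, 0.6), 32, 32)
  set.seed(56)
  out <- fracdet:::hsv_jitter(img, augment_config(hsv_v = 0.4))
  ratio <- out / img
  expect_lt(diff(range(ratio)), 1e-9)  # single multiplicative gain
  expect_true(all(out >= 0 & out <= 1))
})

test_that("label statistics report counts, correlations and degeneracies", {
  labs <- data.frame(class_id = rep(0:2, c(261, 579, 136)))
  n <- nrow(labs)
  set.seed(57)
  labs$cx <- runif(n, 0.3, 0.7)
  labs$cy <- runif(n, 0.3, 0.7)
  labs$w <- labs$cx             # constructed: cor(cx, w) = 1
  labs$h <- runif(n, 0.1, 0.3)
  st <- label_stats(labs)
  expect_equal(st$counts, c(261, 579, 136))
  expect_equal(st$correlations["cx", "w"], 1)
  expect_equal(sum(st$center_hist), n)
  # all-identical boxes: zero variance flagged, correlations reported as 0
  same <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  st2 <- label_stats(same[rep(1, 10), ])
  expect_true(all(st2$constant_attrs))
  expect_equal(st2$correlations["cx", "cy"], 0)
  expect_error(label_stats(same[0, ]), "no labels")
})

test_that("labelme rectangles convert to normalized YOLO rows", {
  j <- list(imageHeight = 200, imageWidth = 400,
            shapes = list(list(label = "A2",
                               points = list(list(40, 20), list(140, 120)))))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(j, f, auto_unbox = TRUE)
  lb <- labelme_to_yolo(f)
  expect_equal(lb$class_id, 1L)
  expect_equal(lb$cx, 90 / 400)
  expect_equal(lb$cy, 70 / 200)
  expect_equal(lb$w, 100 / 400)
  expect_equal(lb$h, 100 / 200)
})
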