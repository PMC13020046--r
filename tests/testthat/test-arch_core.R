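# Architecture: block contracts, graph assembly, forward shapes, decoding.

test_that("conv block obeys its closed-form parameter count and validation", {
  s <- conv_block_spec(16, 32, kernel = 3, stride = 2)
  expect_equal(conv_block_params(s), 4672)
  expect_equal(block_params(build_conv_block(s)), 4672L)
  s2 <- conv_block_spec(64, 128, kernel = 1, stride = 1)
  expect_equal(conv_block_params(s2), 8448)
  expect_equal(block_params(build_conv_block(s2)), 8448L)
  expect_error(conv_block_spec(16, 32, kernel = 2), "kernel")
  expect_error(conv_block_spec(0, 32), "positive")
})

test_that("ADown halves spatial dims, restores channels, rejects odd splits", {
  set.seed(11)
  sp <- adown_spec(64, 128)
  blk <- build_adown_block(sp)
  x <- array(rnorm(80 * 80 * 64), c(80, 80, 64))
  y <- block_forward(blk, x, train = TRUE)
  expect_equal(dim(y), c(40, 40, 128))
  expect_true(all(is.finite(y)))
  expect_error(adown_spec(63, 128), "even")
  expect_error(adown_spec(64, 127), "even")
  small <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  expect_error(block_forward(blk, small), ">= 4")
})

test_that("ADown parameter count matches the layer-counting closed form", {
  sp <- adown_spec(128, 256)
  # 3x3 conv branch + its norm, 1x1 fusion conv + its norm
  expect_equal(adown_params(sp), 9 * 64 * 128 + 64 * 128 + 2 * 128 + 2 * 128)
  expect_equal(adown_params(sp), 82432)
  expect_equal(block_params(build_adown_block(sp)), 82432L)
})

test_that("ADown is cheaper than the plain stride-2 conv for any even pair", {
  for (c_in in c(16, 32, 64, 96, 128, 256)) {
    for (c_out in c(16, 32, 64, 128, 256)) {
      expect_lt(adown_params(adown_spec(c_in, c_out)),
                conv_block_params(conv_block_spec(c_in, c_out, 3, 2)))
    }
  }
})

test_that("ADown and conv downsampling agree on output shapes", {
  set.seed(12)
  for (rep in 1:5) {
    c_in <- sample(c(16, 32, 64), 1)
    c_out <- sample(c(32, 64, 128), 1)
    hw <- sample(c(8, 16, 24, 40), 2, replace = TRUE)
    x <- array(rnorm(hw[1] * hw[2] * c_in), c(hw[1], hw[2], c_in))
    ya <- block_forward(build_adown_block(adown_spec(c_in, c_out)), x)
    yc <- block_forward(build_conv_block(conv_block_spec(c_in, c_out, 3, 2)), x)
    expect_equal(dim(ya), dim(yc))
    expect_equal(dim(ya), c(hw[1] %/% 2, hw[2] %/% 2, c_out))
  }
})

test_that("model assembly validates the replacement set and is deterministic", {
  expect_error(model_config(replacement_set = "stem"), "stem")
  expect_error(model_config(replacement_set = c("P3", "X9")), "unknown")
  expect_silent(model_config(replacement_set = adown_default_sites()))
  set.seed(5)
  m1 <- assemble_model(model_config())
  set.seed(5)
  m2 <- assemble_model(model_config())
  expect_identical(count_parameters(m1), count_parameters(m2))
  expect_identical(m1$params, m2$params)
})

test_that("forward produces three pyramid levels at strides 8/16/32", {
  set.seed(6)
  m <- assemble_model(model_config())
  x <- array(runif(160 * 160 * 3), c(160, 160, 3, 1))
  raw <- model_forward(m, x)
  expect_named(raw, c("p8", "p16", "p32"))
  expect_equal(dim(raw$p8$box)[1:2], c(20, 20))
  expect_equal(dim(raw$p16$box)[1:2], c(10, 10))
  expect_equal(dim(raw$p32$box)[1:2], c(5, 5))
  expect_equal(dim(raw$p8$box)[3], 64)   # 4 * reg_max
  expect_equal(dim(raw$p8$cls)[3], 3)
  bad <- array(0, c(100, 100, 3, 1))
  expect_error(model_forward(m, bad), "divisible by 32")
  # grid arithmetic at the nominal input size, from the shape propagation
  sh <- fracdet:::graph_shapes(m, c(640, 640))
  expect_equal(sh[m$heads$p8$cls, ], c(80, 80))
  expect_equal(sh[m$heads$p16$cls, ], c(40, 40))
  expect_equal(sh[m$heads$p32$cls, ], c(20, 20))
})

test_that("forward on constant input stays finite at all levels", {
  set.seed(7)
  m <- assemble_model(model_config(replacement_set = adown_default_sites()))
  x <- array(0, c(96, 96, 3, 1))
  raw <- model_forward(m, x, train = FALSE)
  for (lv in raw) {
    expect_true(all(is.finite(lv$box)))
    expect_true(all(is.finite(lv$cls)))
  }
})

test_that("backpropagation matches finite differences on a small graph", {
  set.seed(42)
  b <- fracdet:::new_graph_builder()
  i0 <- b$input(3)
  c1 <- b$conv(i0, 3, 4, k = 3, stride = 2, name = "c1")
  c2 <- b$conv(c1, 4, 6, k = 1, stride = 1, name = "c2")
  mdl <- structure(list(nodes = b$nodes, params = b$params,
                        channels = b$channels), class = "fracdet_model")
  for (i in seq_along(mdl$nodes)) {
    if (mdl$nodes[[i]]$kind != "conv") next
    mdl$params[[i]]$w[] <- rnorm(length(mdl$params[[i]]$w), sd = 0.3)
    mdl$params[[i]]$gamma <- runif(length(mdl$params[[i]]$gamma), 0.5, 1.5)
    mdl$params[[i]]$beta <- rnorm(length(mdl$params[[i]]$beta), sd = 0.1)
  }
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  fw0 <- fracdet:::graph_forward(mdl, x, train = TRUE, cache = TRUE)
  R <- array(rnorm(length(fw0$acts[[c2]])), dim(fw0$acts[[c2]]))
  lossfun <- function(m) {
    fw <- fracdet:::graph_forward(m, x, train = TRUE, cache = FALSE)
    sum(fw$acts[[c2]] * R)
  }
  gr <- fracdet:::graph_backward(mdl, fw0$acts, fw0$caches,
                                 setNames(list(R), as.character(c2)))
  for (i in c(c1, c2)) {
    for (f in c("w", "gamma", "beta")) {
      p <- mdl$params[[i]][[f]]
      for (k in sample(length(p), min(3, length(p)))) {
        e <- 1e-5
        mp <- mdl; mp$params[[i]][[f]][k] <- p[k] + e
        mm <- mdl; mm$params[[i]][[f]][k] <- p[k] - e
        num <- (lossfun(mp) - lossfun(mm)) / (2 * e)
        expect_equal(gr[[i]][[f]][k], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("postprocess decodes one-hot distributions and suppresses duplicates", {
  reg_max <- 16
  h <- 4; w <- 4; stride <- 8
  mk_raw <- function(box_logits, cls_logits) {
    list(p8 = list(box = box_logits, cls = cls_logits, stride = stride))
  }
  box <- array(0, c(h, w, 4 * reg_max, 1))
  cls <- array(-20, c(h, w, 2, 1))
  # cell (2, 2): one-hot mass on bin 3 for every edge -> distance 3 * stride
  k <- 3
  for (e in 0:3) box[2, 2, e * reg_max + k + 1, 1] <- 50
  cls[2, 2, 1, 1] <- 5
  det <- postprocess(mk_raw(box, cls), conf_thresh = 0.25, iou_thresh = 0.45)
  expect_equal(nrow(det), 1)
  cx <- (2 - 0.5) * stride; cy <- (2 - 0.5) * stride
  img_side <- h * stride
  expect_equal(as.numeric(det[1, c("x1", "y1", "x2", "y2")]),
               pmin(pmax(c(cx - k * stride, cy - k * stride, cx + k * stride,
                           cy + k * stride), 0), img_side))
  # duplicate detection at another cell with lower confidence is suppressed
  cls2 <- cls
  cls2[2, 3, 1, 1] <- 4  # neighbouring cell, same decoded box (shifted 8 px)
  for (e in 0:3) box[2, 3, e * reg_max + k + 1, 1] <- 50
  det2 <- postprocess(mk_raw(box, cls2), conf_thresh = 0.25, iou_thresh = 0.3)
  expect_equal(nrow(det2), 1)
  expect_equal(det2$confidence, max(det2$confidence))
  # everything below threshold -> empty
  det3 <- postprocess(mk_raw(array(0, dim(box)), array(-20, dim(cls))),
                      conf_thresh = 0.25, iou_thresh = 0.45)
  expect_equal(nrow(det3), 0)
})

test_that("checkpoints round-trip to identical forward outputs", {
  set.seed(9)
  m <- assemble_model(model_config(replacement_set = "P5"))
  x <- array(runif(96 * 96 * 3), c(96, 96, 3, 1))
  r1 <- model_forward(m, x)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  r2 <- model_forward(m2, x)
  expect_identical(r1, r2)
  expect_equal(m2$config$replacement_set, "P5")
})
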