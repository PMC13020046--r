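# Training: SGD with momentum, cosine schedule with linear warmup, batch
# assembly with optional augmentation, and hand-written backpropagation
# through the graph engine.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize the accepted dataset forms to a list of in-memory items
# (image matrix + normalized labels).
as_training_items <- function(dataset, split = "train") {
  if (inherits(dataset, "fracdet_manifest")) {
    sel <- which(dataset$split == split)
    if (!length(sel)) sel <- seq_along(dataset$image_paths)
    return(lapply(sel, function(i) {
      list(image = load_image_gray(dataset$image_paths[i]),
           labels = read_yolo_labels(dataset$label_paths[i],
                                     num_classes = length(dataset$class_names)))
    }))
  }
  if (is.list(dataset) && length(dataset) &&
      all(vapply(dataset, function(d) is.list(d) && !is.null(d$image), TRUE))) {
    return(dataset)
  }
  stop("dataset must be a fracdet_manifest or a list of image/labels items")
}

sample_item <- function(items, cfg, aug) {
  if (!is.null(aug) && stats::runif(1) < aug$mosaic && length(items) >= 4) {
    picks <- c(sample(length(items), 1), sample(length(items), 3, replace = TRUE))
    ms <- mosaic_and_affine(lapply(items[picks], `[[`, "image"),
                            lapply(items[picks], `[[`, "labels"),
                            aug)
    it <- list(image = ms$image, labels = ms$labels)
  } else {
    it <- items[[sample(length(items), 1)]]
    if (!is.null(aug)) it$image <- hsv_jitter(it$image, aug)
  }
  if (!is.null(aug) && stats::runif(1) < aug$fliplr) {
    fl <- hflip(it$image, it$labels)
    it <- list(image = fl$image, labels = fl$labels)
  }
  it
}

make_batch <- function(items, idx, config, aug) {
  B <- length(idx)
  x <- array(0, c(config$imgsz, config$imgsz, 3, B))
  gt <- vector("list", B)
  for (k in seq_len(B)) {
    it <- if (is.null(aug)) items[[idx[k]]] else sample_item(items, config, aug)
    lb <- preprocess(it$image, config$imgsz)
    x[, , , k] <- lb$x
    gt[[k]] <- if (nrow(it$labels)) boxes_to_input(it$labels, lb) else
      data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                 x2 = numeric(0), y2 = numeric(0))
  }
  list(x = x, gt = gt)
}

sgd_update <- function(model, grads, state, lr, config) {
  mom <- config$momentum
  wd <- config$weight_decay
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (f in names(g)) {
      gi <- g[[f]]
      if (f == "w") gi <- gi + wd * model$params[[i]][[f]]
      key <- paste0(i, ".", f)
      v <- state[[key]]
      v <- if (is.null(v)) -lr * gi else mom * v - lr * gi
      state[[key]] <- v
      model$params[[i]][[f]] <- model$params[[i]][[f]] + v
    }
  }
  list(model = model, state = state)
}

# One gradient step on a prepared batch; returns updated model + breakdown.
train_step <- function(model, batch, config, state, lr) {
  fw <- graph_forward(model, batch$x, train = TRUE, cache = TRUE)
  for (nm in names(fw$new_buffers)) {
    i <- as.integer(nm)
    model$params[[i]]$rm <- fw$new_buffers[[nm]]$rm
    model$params[[i]]$rv <- fw$new_buffers[[nm]]$rv
  }
  raw <- lapply(model$heads, function(h) {
    list(box = fw$acts[[h$box]], cls = fw$acts[[h$cls]], stride = h$stride)
  })
  ls <- detection_loss(raw, batch$gt, config, with_grads = TRUE)
  grad_out <- list()
  for (lv in names(model$heads)) {
    grad_out[[as.character(model$heads[[lv]]$box)]] <- ls$grads[[lv]]$box
    grad_out[[as.character(model$heads[[lv]]$cls)]] <- ls$grads[[lv]]$cls
  }
  grads <- graph_backward(model, fw$acts, fw$caches, grad_out)
  up <- sgd_update(model, grads, state, lr, config)
  list(model = up$model, state = up$state, breakdown = ls$breakdown)
}

#' Train a detector
#'
#' Seeded SGD training: cosine learning-rate annealing with linear warmup,
#' momentum, weight decay on convolution kernels, optional mosaic /
#' horizontal-flip / value-jitter augmentation, and per-iteration loss
#' logging. All randomness (shuffling, augmentation draws) derives from
#' `config$seed`, so two runs with the same seed produce identical loss
#' sequences.
#'
#' @param model a `fracdet_model` from [assemble_model()].
#' @param dataset a [dataset_manifest()] (its train split is used) or a list
#'   of `list(image =, labels =)` items with normalized labels.
#' @param config a [train_config()].
#' @param weights_dir optional directory for `best.rds` / `last.rds`
#'   checkpoints.
#' @return list: `model` (final weights), `best_model` (lowest total loss),
#'   `log` (data.frame: iteration, epoch, lr, box/cls/dfl/total loss).
#' @export
train_loop <- function(model, dataset, config = train_config(),
                       weights_dir = NULL) {
  items <- as_training_items(dataset)
  if (!length(items)) stop("empty dataset")
  if (config$epochs < 1) stop("epochs must be >= 1")
  set.seed(config$seed)
  aug <- if (config$augment) {
    augment_config(mosaic = config$mosaic)
  } else NULL
  n <- length(items)
  ipe <- max(1L, ceiling(n / config$batch_size))
  total <- config$epochs * ipe
  if (!is.null(config$max_iterations)) {
    total <- min(total, config$max_iterations)
  }
  # warmup never exceeds a tenth of a capped run
  warmup <- min(config$warmup_epochs * ipe, max(1L, ceiling(0.1 * total)))
  state <- list()
  log <- vector("list", total)
  best <- list(loss = Inf, model = NULL)
  it <- 0L
  for (epoch in seq_len(config$epochs) - 1L) {
    if (it >= total) break
    base_lr <- lr_schedule(epoch, config)
    ord <- sample(n)
    for (bi in seq_len(ipe)) {
      if (it >= total) break
      idx <- ord[((bi - 1L) * config$batch_size + 1L):
                   min(bi * config$batch_size, n)]
      lr <- if (it < warmup) base_lr * (it + 1) / warmup else base_lr
      batch <- make_batch(items, idx, config, aug)
      st <- train_step(model, batch, config, state, lr)
      model <- st$model
      state <- st$state
      it <- it + 1L
      bd <- st$breakdown
      log[[it]] <- data.frame(iteration = it, epoch = epoch, lr = lr,
                              box_loss = bd$box_loss, cls_loss = bd$cls_loss,
                              dfl_loss = bd$dfl_loss, total = bd$total)
      if (bd$total < best$loss) {
        best <- list(loss = bd$total, model = model)
      }
    }
  }
  log <- do.call(rbind, log[seq_len(it)])
  if (!is.null(weights_dir)) {
    dir.create(weights_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(model, file.path(weights_dir, "last.rds"))
    save_checkpoint(best$model %||% model, file.path(weights_dir, "best.rds"))
    utils::write.csv(log, file.path(weights_dir, "results.csv"),
                     row.names = FALSE)
  }
  list(model = model, best_model = best$model %||% model, log = log)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a flat named map of parameter arrays plus the model
#' configuration; reloading reproduces identical forward outputs.
#'
#' @param model a `fracdet_model`.
#' @param path checkpoint file.
#' @export
save_checkpoint <- function(model, path) {
  flat <- list()
  for (i in seq_along(model$params)) {
    p <- model$params[[i]]
    if (is.null(p)) next
    for (f in names(p)) flat[[paste0("n", i, ".", f)]] <- p[[f]]
  }
  saveRDS(list(config = unclass(model$config), params = flat), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the restored `fracdet_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config)
  model <- assemble_model(cfg, init_weights = FALSE)
  for (nm in names(ck$params)) {
    m <- regmatches(nm, regexec("^n([0-9]+)\\.(.+)$", nm))[[1]]
    i <- as.integer(m[2])
    model$params[[i]][[m[3]]] <- ck$params[[nm]]
  }
  model
}

#' Run inference over a dataset
#'
#' @param model a trained `fracdet_model`.
#' @param dataset manifest or item list (see [train_loop()]).
#' @param split which manifest split to use.
#' @param imgsz input size.
#' @param conf_thresh,iou_thresh decoding thresholds.
#' @return list: `detections` (data.frame over all images) and `ground_truth`
#'   (data.frame `image_id, class_id, x1, y1, x2, y2` in input pixels).
#' @export
predict_dataset <- function(model, dataset, split = "val", imgsz = 160,
                            conf_thresh = 0.001, iou_thresh = 0.45) {
  items <- as_training_items(dataset, split = split)
  dets <- list()
  gts <- list()
  for (i in seq_along(items)) {
    lb <- preprocess(items[[i]]$image, imgsz)
    raw <- model_forward(model, lb$x, train = FALSE)
    d <- postprocess(raw, conf_thresh, iou_thresh, image_id = i)
    dets[[i]] <- d
    g <- items[[i]]$labels
    if (nrow(g)) {
      gb <- boxes_to_input(g, lb)
      gts[[i]] <- data.frame(image_id = i, gb)
    }
  }
  list(detections = do.call(rbind, dets),
       ground_truth = do.call(rbind, gts))
}
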