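# Deterministic parameter / multiply-accumulate accounting over the model
# graph. Counts follow the conventions customary for this detector family:
# parameters are learnable scalars only (conv kernels, batch-norm scale and
# shift, head biases; running statistics and the fixed DFL projection are
# buffers); MACs are counted for convolution layers only, one MAC per output
# element per kernel tap (kernel^2 * in_channels), with pooling, activation,
# normalization and upsampling excluded; FLOPs = 2 * MACs.

learnable_names <- c("w", "b", "gamma", "beta")

#' Count learnable parameters
#'
#' Sums every learnable scalar in the model: convolution kernels, batch-norm
#' scale/shift and head biases. Batch-norm running statistics are buffers and
#' are not counted.
#'
#' @param model a `fracdet_model` (or a single built block).
#' @return integer scalar.
#' @export
count_parameters <- function(model) {
  tot <- 0
  for (p in model$params) {
    if (is.null(p)) next
    for (nm in intersect(names(p), learnable_names)) tot <- tot + length(p[[nm]])
  }
  as.integer(tot)
}

# Propagate spatial dims through the graph; returns a (nodes x 2) matrix.
graph_shapes <- function(model, input_hw) {
  nodes <- model$nodes
  sh <- matrix(0L, length(nodes), 2)
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    sh[i, ] <- switch(
      nd$kind,
      input = as.integer(input_hw),
      conv = (sh[nd$from, ] + 2L * nd$pad - nd$k) %/% nd$stride + 1L,
      maxpool = (sh[nd$from, ] + 2L * nd$pad - nd$k) %/% nd$stride + 1L,
      avgpool2 = sh[nd$from, ] - 1L,
      upsample2 = 2L * sh[nd$from, ],
      split = sh[nd$from, ],
      concat = sh[nd$from[1], ],
      add = sh[nd$from[1], ]
    )
  }
  sh
}

#' Per-layer accounting report
#'
#' @param model a `fracdet_model`.
#' @param input_hw input spatial size `c(H, W)`; both divisible by 32.
#' @return a `fracdet_accounting` list: `per_layer` data.frame
#'   (`name`, `kind`, `param_count`, `mac_count`), `total_params`,
#'   `total_macs`, `total_gflops`, `input_hw`.
#' @export
accounting_report <- function(model, input_hw = c(640, 640)) {
  if (length(input_hw) == 1) input_hw <- rep(input_hw, 2)
  sh <- graph_shapes(model, input_hw)
  nodes <- model$nodes
  nm <- character(0)
  kindv <- character(0)
  pc <- numeric(0)
  mc <- numeric(0)
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$kind == "input") next
    p <- model$params[[i]]
    np <- 0
    if (!is.null(p)) {
      for (f in intersect(names(p), learnable_names)) np <- np + length(p[[f]])
    }
    macs <- 0
    if (nd$kind == "conv") {
      macs <- as.numeric(nd$k)^2 * nd$cin * nd$cout * prod(sh[i, ])
    }
    layer <- if (nzchar(nd$name)) nd$name else paste0("node", i)
    j <- match(layer, nm)
    if (is.na(j)) {
      nm <- c(nm, layer)
      kindv <- c(kindv, nd$kind)
      pc <- c(pc, np)
      mc <- c(mc, macs)
    } else {
      pc[j] <- pc[j] + np
      mc[j] <- mc[j] + macs
      if (kindv[j] != nd$kind) kindv[j] <- "composite"
    }
  }
  structure(list(per_layer = data.frame(name = nm, kind = kindv,
                                        param_count = pc, mac_count = mc),
                 total_params = sum(pc),
                 total_macs = sum(mc),
                 total_gflops = 2 * sum(mc) / 1e9,
                 input_hw = as.integer(input_hw)),
            class = "fracdet_accounting")
}

#' @export
print.fracdet_accounting <- function(x, ...) {
  cat(sprintf("<accounting at %dx%d> params %s (%.2fM), %.1f GFLOPs\n",
              x$input_hw[1], x$input_hw[2],
              format(x$total_params, big.mark = ","),
              x$total_params / 1e6, x$total_gflops))
  invisible(x)
}

#' Estimate FLOPs
#'
#' GFLOPs at the given input size under the 2-FLOPs-per-MAC convention,
#' convolution layers only.
#'
#' @inheritParams accounting_report
#' @return numeric scalar (GFLOPs, unrounded).
#' @export
estimate_gflops <- function(model, input_hw = c(640, 640)) {
  if (length(input_hw) == 1) input_hw <- rep(input_hw, 2)
  if (any(input_hw %% 32 != 0)) {
    stop("input dims must be divisible by 32, got ",
         paste(input_hw, collapse = "x"))
  }
  accounting_report(model, input_hw)$total_gflops
}

#' Compare two accounting reports
#'
#' @param report_a,report_b baseline and variant [accounting_report()]s at
#'   the same input size.
#' @return list with `param_reduction_pct` and `flop_reduction_pct`,
#'   `100 * (a - b) / a` computed from unrounded totals and rounded to one
#'   decimal.
#' @export
compare_models <- function(report_a, report_b) {
  if (!identical(report_a$input_hw, report_b$input_hw)) {
    stop("reports were taken at different input sizes")
  }
  if (report_a$total_params == 0 || report_a$total_macs == 0) {
    stop("baseline report has zero totals")
  }
  list(param_reduction_pct =
         round(100 * (report_a$total_params - report_b$total_params) /
                 report_a$total_params, 1),
       flop_reduction_pct =
         round(100 * (report_a$total_macs - report_b$total_macs) /
                 report_a$total_macs, 1))
}

#' Calibrate the ADown replacement set against printed budgets
#'
#' Enumerates every subset of the six replaceable downsample sites, computes
#' each variant's parameter and FLOP totals analytically, and returns the
#' subset minimizing the summed relative deviation from the target budgets.
#' No single subset reproduces both published figures exactly (parameter
#' savings are dominated by the deep, wide sites while FLOP savings are
#' dominated by site count, since every backbone downsampler costs the same
#' MACs); the calibration therefore optimizes both jointly.
#'
#' @param params_target_m target parameter budget in millions.
#' @param gflops_target target GFLOPs at `input_hw`.
#' @param config base configuration (replacement set ignored).
#' @param input_hw accounting input size.
#' @return list: `sites`, `params_m`, `gflops`, and the full search `table`.
#' @export
calibrate_replacement_set <- function(params_target_m = 2.64,
                                      gflops_target = 7.3,
                                      config = model_config(),
                                      input_hw = c(640, 640)) {
  sites <- c("P2", "P3", "P4", "P5", "N4", "N5")
  best <- NULL
  rows <- list()
  for (mask in 0:(2^length(sites) - 1)) {
    sel <- sites[bitwAnd(mask, 2^(seq_along(sites) - 1)) > 0]
    cfg <- model_config(num_classes = config$num_classes,
                        width_multiple = config$width_multiple,
                        depth_multiple = config$depth_multiple,
                        max_channels = config$max_channels,
                        reg_max = config$reg_max,
                        input_channels = config$input_channels,
                        replacement_set = sel)
    rep <- accounting_report(assemble_model(cfg, init_weights = FALSE), input_hw)
    pm <- rep$total_params / 1e6
    gf <- rep$total_gflops
    score <- abs(pm / params_target_m - 1) + abs(gf / gflops_target - 1)
    rows[[length(rows) + 1L]] <- data.frame(
      sites = paste(sel, collapse = "+"), params_m = pm, gflops = gf,
      score = score)
    if (is.null(best) || score < best$score) {
      best <- list(sites = sel, params_m = pm, gflops = gf, score = score)
    }
  }
  best$table <- do.call(rbind, rows)
  best
}
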