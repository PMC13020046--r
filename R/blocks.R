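# Standalone building blocks: plain stride-2 conv downsampling vs. ADown.
# Both are small self-contained graphs so they can be run and counted in
# isolation from a full detector.

#' Specification of a conv -> batch norm -> SiLU block
#'
#' @param in_channels,out_channels positive channel counts.
#' @param kernel 1 or 3.
#' @param stride 1 or 2.
#' @return a `fracdet_conv_spec`; its learnable parameter count follows the
#'   closed form `kernel^2 * in * out + 2 * out` (kernel weights plus batch
#'   norm scale and shift; the convolution carries no bias).
#' @export
conv_block_spec <- function(in_channels, out_channels, kernel = 3, stride = 2) {
  if (in_channels < 1 || out_channels < 1) stop("channel counts must be positive")
  if (!kernel %in% c(1, 3)) stop("kernel must be 1 or 3")
  if (!stride %in% c(1, 2)) stop("stride must be 1 or 2")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 padding = as.integer(kernel %/% 2)),
            class = "fracdet_conv_spec")
}

#' @rdname conv_block_spec
#' @param spec a block spec.
#' @export
conv_block_params <- function(spec) {
  spec$kernel^2 * spec$in_channels * spec$out_channels + 2 * spec$out_channels
}

#' Specification of an ADown downsampling block
#'
#' The block applies 2x2 stride-1 average pooling, splits the channels into
#' two halves, sends the first half through a 3x3 stride-2 max pool followed
#' by a 1x1 fusion conv block, the second half through a 3x3 stride-2 conv
#' block, and concatenates the two halves.
#'
#' @param in_channels,out_channels even positive channel counts.
#' @return a `fracdet_adown_spec`; learnable parameters follow the closed
#'   form `2.5 * in * out + 2 * out` (9/4 in*out + out/2 for the conv branch,
#'   1/4 in*out + out/2 for the pool branch's fusion conv, each with batch
#'   norm scale/shift).
#' @export
adown_spec <- function(in_channels, out_channels) {
  if (in_channels < 1 || out_channels < 1) stop("channel counts must be positive")
  if (in_channels %% 2 != 0 || out_channels %% 2 != 0) {
    stop("ADown requires even in/out channel counts, got ",
         in_channels, " -> ", out_channels)
  }
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "fracdet_adown_spec")
}

#' @rdname adown_spec
#' @param spec a block spec.
#' @export
adown_params <- function(spec) {
  h_in <- spec$in_channels %/% 2
  h_out <- spec$out_channels %/% 2
  (9 * h_in * h_out + 2 * h_out) + (h_in * h_out + 2 * h_out)
}

#' Realize a block spec as a runnable module
#'
#' @param spec a [conv_block_spec()] or [adown_spec()].
#' @return a `fracdet_block` holding a tiny graph; run it with
#'   [block_forward()], count it with [block_params()].
#' @export
build_conv_block <- function(spec) {
  stopifnot(inherits(spec, "fracdet_conv_spec"))
  b <- new_graph_builder()
  img <- b$input(spec$in_channels)
  b$conv(img, spec$in_channels, spec$out_channels, k = spec$kernel,
         stride = spec$stride, name = "conv_block")
  finish_block(b, spec)
}

#' @rdname build_conv_block
#' @export
build_adown_block <- function(spec) {
  stopifnot(inherits(spec, "fracdet_adown_spec"))
  b <- new_graph_builder()
  img <- b$input(spec$in_channels)
  bld_adown(b, img, spec$in_channels, spec$out_channels, "adown")
  finish_block(b, spec)
}

finish_block <- function(b, spec) {
  block <- structure(list(spec = spec, nodes = b$nodes, params = b$params,
                          channels = b$channels),
                     class = c("fracdet_block", "fracdet_model"))
  for (i in seq_along(block$nodes)) {
    nd <- block$nodes[[i]]
    if (nd$kind != "conv") next
    block$params[[i]]$w[] <- stats::rnorm(length(block$params[[i]]$w),
                                          sd = sqrt(2 / (nd$k^2 * nd$cin)))
  }
  block
}

#' @rdname build_conv_block
#' @param block a built block.
#' @param x feature map, array `(H, W, C)` or `(H, W, C, N)`.
#' @param train use batch statistics in batch norm.
#' @export
block_forward <- function(block, x, train = FALSE) {
  stopifnot(inherits(block, "fracdet_block"))
  d <- dim(x)
  squeeze <- length(d) == 3L
  if (squeeze) dim(x) <- c(d, 1L)
  d <- dim(x)
  cin <- block$spec$in_channels
  if (d[3] != cin) {
    stop("input has ", d[3], " channels; block expects ", cin)
  }
  if (inherits(block$spec, "fracdet_adown_spec")) {
    if (d[1] < 4 || d[2] < 4) stop("spatial dims must be >= 4 for ADown")
    if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
      stop("spatial dims must be even for ADown, got ", d[1], "x", d[2])
    }
  }
  fw <- graph_forward(block, x, train = train, cache = FALSE)
  y <- fw$acts[[length(fw$acts)]]
  if (squeeze) {
    dy <- dim(y)
    dim(y) <- dy[1:3]
  }
  y
}

#' @rdname build_conv_block
#' @export
block_params <- function(block) {
  count_parameters(block)
}
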