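# Elementwise / per-channel primitives used by the graph engine. The hot
# paths are C++ (single pass, no intermediate copies); see src/ops.cpp.
# Feature maps are arrays with dim (H, W, C, N).

silu <- function(a) cpp_silu_fwd(a)

silu_bwd <- function(a, dy) cpp_silu_bwd(a, dy)

add_channel_bias <- function(z, b) cpp_bias_add(z, b)

channel_sums <- function(z) {
  d <- dim(z)
  cs <- .colSums(matrix(z, nrow = d[1] * d[2]), d[1] * d[2], d[3] * d[4])
  .rowSums(matrix(cs, d[3], d[4]), d[3], d[4])
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.03

# Batch normalization over (H, W, N) per channel.
# train mode returns caches for the backward pass and updated running stats.
batchnorm_fwd <- function(z, gamma, beta, rm, rv, train) {
  if (train) {
    r <- cpp_bn_fwd_train(z, gamma, beta, BN_EPS)
    n_el <- prod(dim(z)[c(1, 2, 4)])
    unbias <- if (n_el > 1) n_el / (n_el - 1) else 1
    list(y = r$y, xhat = r$xhat, invstd = r$invstd,
         rm = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * r$mu,
         rv = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * r$var * unbias)
  } else {
    list(y = cpp_bn_fwd_eval(z, gamma, beta, rm, rv, BN_EPS))
  }
}

batchnorm_bwd <- function(dy, xhat, invstd, gamma) {
  cpp_bn_bwd(dy, xhat, invstd, gamma)
}

# Concatenate feature maps along the channel axis.
concat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(a) dim(a)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (a in xs) {
    nc <- dim(a)[3]
    out[, , (off + 1L):(off + nc), ] <- a
    off <- off + nc
  }
  out
}
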