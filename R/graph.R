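# Minimal dataflow-graph engine. A model is a list of nodes in topological
# order (every `from` index precedes the node); parameters live in a list
# parallel to the nodes so that the optimizer can address them uniformly.

new_graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$params <- list()
  env$channels <- integer()

  push <- function(node, par = NULL, out_ch) {
    i <- length(env$nodes) + 1L
    env$nodes[[i]] <- node
    env$params[[i]] <- par
    env$channels[i] <- as.integer(out_ch)
    i
  }

  env$input <- function(channels) {
    push(list(kind = "input"), out_ch = channels)
  }
  # conv -> (optional) batch norm -> (optional) SiLU, fused into one node
  env$conv <- function(from, cin, cout, k, stride, pad = k %/% 2,
                       bn = TRUE, act = TRUE, bias = !bn, name = "") {
    stopifnot(cin >= 1, cout >= 1, k %in% c(1L, 3L))
    if (env$channels[from] != cin) {
      stop(sprintf("conv '%s': expected %d input channels, node supplies %d",
                   name, cin, env$channels[from]))
    }
    par <- list(w = array(0, c(k, k, cin, cout)))
    if (bias) par$b <- numeric(cout)
    if (bn) {
      par$gamma <- rep(1, cout)
      par$beta <- numeric(cout)
    }
    node <- list(kind = "conv", from = from, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad),
                 cin = as.integer(cin), cout = as.integer(cout),
                 bn = bn, act = act, bias = bias, name = name)
    i <- push(node, par, cout)
    if (bn) {
      env$params[[i]]$rm <- numeric(cout)  # running stats (buffers, not learnable)
      env$params[[i]]$rv <- rep(1, cout)
    }
    i
  }
  env$maxpool <- function(from, k, stride, pad, name = "") {
    push(list(kind = "maxpool", from = from, k = as.integer(k),
              stride = as.integer(stride), pad = as.integer(pad), name = name),
         out_ch = env$channels[from])
  }
  env$avgpool2 <- function(from, name = "") {
    push(list(kind = "avgpool2", from = from, name = name),
         out_ch = env$channels[from])
  }
  env$upsample2 <- function(from, name = "") {
    push(list(kind = "upsample2", from = from, name = name),
         out_ch = env$channels[from])
  }
  env$split <- function(from, ch_from, ch_to, name = "") {
    push(list(kind = "split", from = from, ch_from = as.integer(ch_from),
              ch_to = as.integer(ch_to), name = name),
         out_ch = ch_to - ch_from + 1L)
  }
  env$concat <- function(froms, name = "") {
    push(list(kind = "concat", from = as.integer(froms), name = name),
         out_ch = sum(env$channels[froms]))
  }
  env$add <- function(a, b, name = "") {
    stopifnot(env$channels[a] == env$channels[b])
    push(list(kind = "add", from = c(a, b), name = name),
         out_ch = env$channels[a])
  }
  env
}

#' @keywords internal
graph_forward <- function(model, x, train = FALSE, cache = train,
                          keep = NULL) {
  nodes <- model$nodes
  params <- model$params
  acts <- vector("list", length(nodes))
  caches <- if (cache) vector("list", length(nodes)) else NULL
  new_buffers <- if (train) list() else NULL
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    acts[[i]] <- switch(
      nd$kind,
      input = x,
      conv = {
        p <- params[[i]]
        z <- cpp_conv2d_fwd(acts[[nd$from]], p$w, nd$stride, nd$pad)
        if (nd$bias) z <- add_channel_bias(z, p$b)
        if (nd$bn) {
          bo <- batchnorm_fwd(z, p$gamma, p$beta, p$rm, p$rv, train)
          if (cache) caches[[i]] <- list(xhat = bo$xhat, invstd = bo$invstd)
          if (train) new_buffers[[as.character(i)]] <- list(rm = bo$rm, rv = bo$rv)
          z <- bo$y
        }
        if (nd$act) {
          if (cache) {
            sf <- cpp_silu_fwd_cache(z)
            caches[[i]]$a <- z
            caches[[i]]$s <- sf$s
            z <- sf$y
          } else {
            z <- silu(z)
          }
        }
        z
      },
      maxpool = {
        r <- cpp_maxpool_fwd(acts[[nd$from]], nd$k, nd$stride, nd$pad)
        if (cache) caches[[i]] <- list(idx = r$idx, in_dim = dim(acts[[nd$from]]))
        r$y
      },
      avgpool2 = cpp_avgpool2_fwd(acts[[nd$from]]),
      upsample2 = cpp_upsample2_fwd(acts[[nd$from]]),
      split = acts[[nd$from]][, , nd$ch_from:nd$ch_to, , drop = FALSE],
      concat = concat_channels(acts[nd$from]),
      add = acts[[nd$from[1]]] + acts[[nd$from[2]]],
      stop("unknown node kind: ", nd$kind)
    )
  }
  list(acts = acts, caches = caches, new_buffers = new_buffers)
}

#' @keywords internal
graph_backward <- function(model, acts, caches, grad_out) {
  nodes <- model$nodes
  params <- model$params
  n <- length(nodes)
  dacts <- vector("list", n)
  grads <- vector("list", n)
  for (nm in names(grad_out)) {
    i <- as.integer(nm)
    dacts[[i]] <- if (is.null(dacts[[i]])) grad_out[[nm]] else dacts[[i]] + grad_out[[nm]]
  }
  acc <- function(j, g) {
    dacts[[j]] <<- if (is.null(dacts[[j]])) g else dacts[[j]] + g
  }
  for (i in rev(seq_len(n))) {
    d <- dacts[[i]]
    if (is.null(d)) next
    nd <- nodes[[i]]
    switch(
      nd$kind,
      input = NULL,
      conv = {
        p <- params[[i]]
        g <- list()
        if (nd$act) d <- cpp_silu_bwd_cached(caches[[i]]$a, caches[[i]]$s, d)
        if (nd$bn) {
          bb <- batchnorm_bwd(d, caches[[i]]$xhat, caches[[i]]$invstd, p$gamma)
          g$gamma <- bb$dgamma
          g$beta <- bb$dbeta
          d <- bb$dz
        }
        if (nd$bias) g$b <- channel_sums(d)
        need_dx <- nodes[[nd$from]]$kind != "input"
        cb <- cpp_conv2d_bwd(acts[[nd$from]], p$w, d, nd$stride, nd$pad, need_dx)
        g$w <- cb$dw
        grads[[i]] <- g
        if (need_dx) acc(nd$from, cb$dx)
      },
      maxpool = {
        id <- caches[[i]]$in_dim
        acc(nd$from, cpp_maxpool_bwd(caches[[i]]$idx, d, id[1], id[2], id[3]))
      },
      avgpool2 = {
        id <- dim(acts[[nd$from]])
        acc(nd$from, cpp_avgpool2_bwd(d, id[1], id[2]))
      },
      upsample2 = acc(nd$from, cpp_upsample2_bwd(d)),
      split = {
        g <- array(0, dim(acts[[nd$from]]))
        g[, , nd$ch_from:nd$ch_to, ] <- d
        acc(nd$from, g)
      },
      concat = {
        off <- 0L
        for (j in nd$from) {
          nc <- dim(acts[[j]])[3]
          acc(j, d[, , (off + 1L):(off + nc), , drop = FALSE])
          off <- off + nc
        }
      },
      add = {
        acc(nd$from[1], d)
        acc(nd$from[2], d)
      }
    )
    dacts[[i]] <- NULL  # free as soon as consumed
  }
  grads
}
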