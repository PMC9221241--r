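# A minimal static computation graph for the segmentation networks.
#
# A graph is a list of primitive nodes (conv, dwconv, bn, relu, sigmoid, se,
# maxpool, upsample, concat, input) in topological order, plus flat named
# lists of parameters, batch-norm running statistics, and gradient buffers.
# Networks are assembled once by the architecture builders; forward and
# backward walk the node list.

#' @noRd
new_graph <- function() {
  list(nodes = list(), params = list(), state = list())
}

#' Append a node; returns the updated graph with `last_id` set.
#' @noRd
g_add <- function(g, op, inputs = integer(0), ...) {
  id <- length(g$nodes) + 1L
  node <- c(list(id = id, op = op, inputs = as.integer(inputs)), list(...))
  node$pname <- sprintf("n%03d", id)
  g$nodes[[id]] <- node
  g$last_id <- id
  g
}

#' He-uniform weight draw.
#' @noRd
he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Create parameters for every node (seeded by the caller via set.seed).
#' @noRd
g_init_params <- function(g) {
  for (node in g$nodes) {
    p <- node$pname
    switch(node$op,
      conv = {
        k <- node$k
        g$params[[paste0(p, "_W")]] <-
          he_uniform(c(k, k, node$in_ch, node$out_ch), k * k * node$in_ch)
        if (isTRUE(node$bias)) {
          g$params[[paste0(p, "_b")]] <- numeric(node$out_ch)
        }
      },
      cbr = {
        k <- node$k
        g$params[[paste0(p, "_W")]] <-
          he_uniform(c(k, k, node$in_ch, node$out_ch), k * k * node$in_ch)
        g$params[[paste0(p, "_gamma")]] <- rep(1, node$out_ch)
        g$params[[paste0(p, "_beta")]] <- numeric(node$out_ch)
        g$state[[paste0(p, "_rmean")]] <- numeric(node$out_ch)
        g$state[[paste0(p, "_rvar")]] <- rep(1, node$out_ch)
      },
      dbr = {
        k <- node$k
        g$params[[paste0(p, "_W")]] <- he_uniform(c(k, k, node$ch), k * k)
        g$params[[paste0(p, "_gamma")]] <- rep(1, node$ch)
        g$params[[paste0(p, "_beta")]] <- numeric(node$ch)
        g$state[[paste0(p, "_rmean")]] <- numeric(node$ch)
        g$state[[paste0(p, "_rvar")]] <- rep(1, node$ch)
      },
      dwconv = {
        k <- node$k
        g$params[[paste0(p, "_W")]] <- he_uniform(c(k, k, node$ch), k * k)
      },
      bn = {
        g$params[[paste0(p, "_gamma")]] <- rep(1, node$ch)
        g$params[[paste0(p, "_beta")]] <- numeric(node$ch)
        g$state[[paste0(p, "_rmean")]] <- numeric(node$ch)
        g$state[[paste0(p, "_rvar")]] <- rep(1, node$ch)
      },
      se = {
        ch <- node$ch; mid <- ch %/% node$reduction
        g$params[[paste0(p, "_W1")]] <- he_uniform(c(ch, mid), ch)
        g$params[[paste0(p, "_b1")]] <- numeric(mid)
        g$params[[paste0(p, "_W2")]] <- he_uniform(c(mid, ch), mid)
        g$params[[paste0(p, "_b2")]] <- numeric(ch)
      }
    )
  }
  g
}

#' Forward pass over the whole graph.
#'
#' @param g graph, @param x input tensor (H,W,C,N).
#' @param train logical; batch statistics (and running-stat updates) vs
#'   running statistics for batch norm.
#' @param keep logical; retain per-node outputs and caches for backward.
#' @param force_se_identity test hook: clamp all SE gates to 1.
#' @return list(out, outs, caches, state).
#' @noRd
g_forward <- function(g, x, train = FALSE, keep = train,
                      force_se_identity = FALSE) {
  n <- length(g$nodes)
  outs <- vector("list", n)
  caches <- if (keep) vector("list", n) else NULL
  state <- g$state
  P <- g$params
  for (node in g$nodes) {
    id <- node$id; p <- node$pname
    y <- switch(node$op,
      input = x,
      conv = {
        r <- conv2d_fwd(outs[[node$inputs]], P[[paste0(p, "_W")]],
                        bias = P[[paste0(p, "_b")]],
                        dilation = node$dilation %||% 1L,
                        return_patches = keep)
        if (keep) {
          caches[[id]] <- r$P
          r$y
        } else r
      },
      dwconv = {
        r <- dwconv_fwd(outs[[node$inputs]], P[[paste0(p, "_W")]],
                        return_patches = keep)
        if (keep) {
          caches[[id]] <- r$P
          r$y
        } else r
      },
      cbr = {
        r <- cbr_fwd(outs[[node$inputs]], P[[paste0(p, "_W")]],
                     P[[paste0(p, "_gamma")]], P[[paste0(p, "_beta")]],
                     state[[paste0(p, "_rmean")]],
                     state[[paste0(p, "_rvar")]], train = train,
                     dilation = node$dilation %||% 1L, keep = keep)
        if (train) {
          state[[paste0(p, "_rmean")]] <- r$rmean
          state[[paste0(p, "_rvar")]] <- r$rvar
        }
        if (keep) caches[[id]] <- r$cache
        r$y
      },
      dbr = {
        r <- dbr_fwd(outs[[node$inputs]], P[[paste0(p, "_W")]],
                     P[[paste0(p, "_gamma")]], P[[paste0(p, "_beta")]],
                     state[[paste0(p, "_rmean")]],
                     state[[paste0(p, "_rvar")]], train = train, keep = keep)
        if (train) {
          state[[paste0(p, "_rmean")]] <- r$rmean
          state[[paste0(p, "_rvar")]] <- r$rvar
        }
        if (keep) caches[[id]] <- r$cache
        r$y
      },
      bn = {
        r <- bn_fwd(outs[[node$inputs]],
                    P[[paste0(p, "_gamma")]], P[[paste0(p, "_beta")]],
                    state[[paste0(p, "_rmean")]], state[[paste0(p, "_rvar")]],
                    train = train)
        if (train) {
          state[[paste0(p, "_rmean")]] <- r$rmean
          state[[paste0(p, "_rvar")]] <- r$rvar
        }
        if (keep) caches[[id]] <- r$cache
        r$y
      },
      relu = relu_fwd(outs[[node$inputs]]),
      sigmoid = sigmoid_fwd(outs[[node$inputs]]),
      se = {
        r <- se_fwd(outs[[node$inputs]],
                    P[[paste0(p, "_W1")]], P[[paste0(p, "_b1")]],
                    P[[paste0(p, "_W2")]], P[[paste0(p, "_b2")]],
                    force_identity = force_se_identity)
        if (keep) caches[[id]] <- r$cache
        r$y
      },
      maxpool = {
        r <- maxpool2_fwd(outs[[node$inputs]])
        if (keep) caches[[id]] <- r$cache
        r$y
      },
      upsample = upsample2_fwd(outs[[node$inputs]]),
      concat = concat_channels(outs[node$inputs]),
      stop("unknown op: ", node$op)
    )
    outs[[id]] <- y
  }
  out_ids <- g$out_ids %||% g$last_id
  list(out = if (length(out_ids) == 1L) outs[[out_ids]] else outs[out_ids],
       outs = if (keep) outs else NULL,
       caches = caches, state = state)
}

#' Backward pass; `fw` is the result of g_forward(..., keep = TRUE) and
#' `d_out` the gradient at the (single) output node.
#' @return list(grads = named list matching g$params, dX = gradient at input).
#' @noRd
g_backward <- function(g, fw, d_out) {
  n <- length(g$nodes)
  outs <- fw$outs; caches <- fw$caches
  P <- g$params
  acc <- vector("list", n)
  out_id <- (g$out_ids %||% g$last_id)[1L]
  acc[[out_id]] <- d_out
  grads <- list()
  dX_input <- NULL
  add_grad <- function(a, d) if (is.null(a)) d else a + d
  for (id in rev(seq_len(n))) {
    node <- g$nodes[[id]]
    dY <- acc[[id]]
    if (is.null(dY)) next
    p <- node$pname
    switch(node$op,
      input = { dX_input <- dY },
      conv = {
        b <- conv2d_bwd(outs[[node$inputs]], P[[paste0(p, "_W")]], dY,
                        bias = isTRUE(node$bias),
                        dilation = node$dilation %||% 1L,
                        P = caches[[id]])
        grads[[paste0(p, "_W")]] <- b$dW
        if (isTRUE(node$bias)) grads[[paste0(p, "_b")]] <- b$db
        acc[[node$inputs]] <- add_grad(acc[[node$inputs]], b$dX)
      },
      dwconv = {
        b <- dwconv_bwd(outs[[node$inputs]], P[[paste0(p, "_W")]], dY,
                        P = caches[[id]])
        grads[[paste0(p, "_W")]] <- b$dW
        acc[[node$inputs]] <- add_grad(acc[[node$inputs]], b$dX)
      },
      cbr = {
        b <- cbr_bwd(caches[[id]], P[[paste0(p, "_W")]],
                     P[[paste0(p, "_gamma")]], dY,
                     dilation = node$dilation %||% 1L)
        grads[[paste0(p, "_W")]] <- b$dW
        grads[[paste0(p, "_gamma")]] <- b$dgamma
        grads[[paste0(p, "_beta")]] <- b$dbeta
        acc[[node$inputs]] <- add_grad(acc[[node$inputs]], b$dX)
      },
      dbr = {
        b <- dbr_bwd(caches[[id]], P[[paste0(p, "_W")]],
                     P[[paste0(p, "_gamma")]], dY)
        grads[[paste0(p, "_W")]] <- b$dW
        grads[[paste0(p, "_gamma")]] <- b$dgamma
        grads[[paste0(p, "_beta")]] <- b$dbeta
        acc[[node$inputs]] <- add_grad(acc[[node$inputs]], b$dX)
      },
      bn = {
        b <- bn_bwd(caches[[id]], P[[paste0(p, "_gamma")]], dY)
        grads[[paste0(p, "_gamma")]] <- b$dgamma
        grads[[paste0(p, "_beta")]] <- b$dbeta
        acc[[node$inputs]] <- add_grad(acc[[node$inputs]], b$dX)
      },
      relu = {
        acc[[node$inputs]] <- add_grad(acc[[node$inputs]],
                                       relu_bwd(outs[[node$inputs]], dY))
      },
      sigmoid = {
        acc[[node$inputs]] <- add_grad(acc[[node$inputs]],
                                       sigmoid_bwd(outs[[id]], dY))
      },
      se = {
        b <- se_bwd(caches[[id]], P[[paste0(p, "_W1")]], P[[paste0(p, "_W2")]], dY)
        if (!is.null(b$dW1)) {
          grads[[paste0(p, "_W1")]] <- b$dW1
          grads[[paste0(p, "_b1")]] <- b$db1
          grads[[paste0(p, "_W2")]] <- b$dW2
          grads[[paste0(p, "_b2")]] <- b$db2
        }
        acc[[node$inputs]] <- add_grad(acc[[node$inputs]], b$dX)
      },
      maxpool = {
        acc[[node$inputs]] <- add_grad(acc[[node$inputs]],
                                       maxpool2_bwd(caches[[id]], dY))
      },
      upsample = {
        din <- dim(outs[[node$inputs]])
        acc[[node$inputs]] <- add_grad(acc[[node$inputs]],
                                       upsample2_bwd(dY, din[1L], din[2L]))
      },
      concat = {
        Cs <- vapply(outs[node$inputs], function(o) dim(o)[3L], integer(1))
        parts <- split_channels(dY, Cs)
        for (i in seq_along(node$inputs)) {
          j <- node$inputs[i]
          acc[[j]] <- add_grad(acc[[j]], parts[[i]])
        }
      }
    )
    acc[[id]] <- NULL  # release
  }
  list(grads = grads, dX = dX_input)
}

# ---- composite builders -----------------------------------------------------

#' conv -> batch norm -> ReLU. Convolutions before batch norm carry no bias
#' (it would be absorbed by the normalization shift).
#' @noRd
g_conv_block <- function(g, input, in_ch, out_ch, k = 3L, dilation = 1L) {
  g_add(g, "cbr", input, in_ch = in_ch, out_ch = out_ch, k = k,
        dilation = dilation)
}

#' Depthwise 3x3 + BN + ReLU, then pointwise 1x1 + BN + ReLU.
#' @noRd
g_dwsep_block <- function(g, input, in_ch, out_ch, k = 3L) {
  g <- g_add(g, "dbr", input, ch = in_ch, k = k)
  g_add(g, "cbr", g$last_id, in_ch = in_ch, out_ch = out_ch, k = 1L)
}

#' Atrous spatial pyramid pooling: parallel 3x3 conv blocks at the given
#' dilation rates, channel concatenation, then a 1x1 conv-block fusion.
#' @noRd
g_aspp <- function(g, input, in_ch, rates, branch_ch, out_ch) {
  branch_ids <- integer(length(rates))
  for (i in seq_along(rates)) {
    g <- g_conv_block(g, input, in_ch, branch_ch, k = 3L,
                      dilation = as.integer(rates[i]))
    branch_ids[i] <- g$last_id
  }
  g <- g_add(g, "concat", branch_ids)
  g_conv_block(g, g$last_id, branch_ch * length(rates), out_ch, k = 1L)
}

# ---- optimiser --------------------------------------------------------------

#' @noRd
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

#' One Adam step; returns list(params, opt).
#' @noRd
adam_step <- function(params, grads, opt, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
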