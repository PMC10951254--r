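# Minimal static-graph convolutional network engine.
#
# A network is a topologically ordered list of nodes; each node applies one
# primitive op to the outputs of earlier nodes. Tensors are R arrays of dim
# (H, W, C, N). Convolutions and bilinear resampling run in C++
# (src/nn_kernels.cpp); everything else is vectorized R.
#
# Supported ops: input, conv, bn, relu, silu, sigmoid, add, concat, gap,
# mul_chan (per-channel gating), up2 (bilinear x2 upsampling).

nn_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$params <- list()
  g$buffers <- list()
  class(g) <- "nn_graph"
  g
}

nn_add <- function(g, op, inputs = integer(0), ...) {
  inputs <- as.integer(inputs)  # force before reading the node count
  id <- length(g$nodes) + 1L
  stopifnot(all(inputs < id), all(inputs >= 1L) || length(inputs) == 0L)
  g$nodes[[id]] <- c(list(id = id, op = op, inputs = inputs), list(...))
  id
}

# ---- shape inference (shapes are c(H, W, C)) --------------------------------

node_out_shape <- function(node, in_shapes) {
  switch(node$op,
    input = node$shape,
    conv = {
      s <- in_shapes[[1]]
      ho <- (s[1] + 2 * node$pad - node$k) %/% node$stride + 1L
      wo <- (s[2] + 2 * node$pad - node$k) %/% node$stride + 1L
      c(ho, wo, node$cout)
    },
    bn = , relu = , silu = , sigmoid = in_shapes[[1]],
    add = in_shapes[[1]],
    concat = {
      s <- in_shapes[[1]]
      c(s[1], s[2], sum(vapply(in_shapes, `[`, 0, 3)))
    },
    gap = c(1L, 1L, in_shapes[[1]][3]),
    mul_chan = in_shapes[[1]],
    up2 = {
      s <- in_shapes[[1]]
      c(2L * s[1], 2L * s[2], s[3])
    },
    stop("unknown op: ", node$op)
  )
}

graph_shapes <- function(g, input_hw) {
  shapes <- vector("list", length(g$nodes))
  for (node in g$nodes) {
    if (node$op == "input") {
      shapes[[node$id]] <- c(input_hw[1], input_hw[2], node$channels)
    } else {
      shapes[[node$id]] <- node_out_shape(node, shapes[node$inputs])
    }
  }
  shapes
}

# ---- parameter bookkeeping --------------------------------------------------

node_param_shapes <- function(node) {
  switch(node$op,
    conv = {
      ps <- list(w = c(node$k, node$k, node$cin %/% node$groups, node$cout))
      if (isTRUE(node$bias)) ps$b <- node$cout
      ps
    },
    bn = list(gamma = node$c, beta = node$c),
    NULL
  )
}

#' Count trainable parameters of a model
#'
#' Exact sum of all trainable weight elements (convolution kernels and biases,
#' batch-norm scales and shifts). Batch-norm running statistics are buffers,
#' not parameters, and are excluded.
#'
#' @param model A model built by [build_se_regunet()], [build_classifier()] or
#'   [build_encoder()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  g <- model$graph
  total <- 0
  for (node in g$nodes) {
    ps <- node_param_shapes(node)
    if (!is.null(ps)) total <- total + sum(vapply(ps, prod, 0))
  }
  as.integer(total)
}

# He-normal init for conv kernels; unit/zero for batch norm.
nn_init_params <- function(model, seed = 1L) {
  g <- model$graph
  old <- rng_push(seed)
  on.exit(rng_pop(old))
  for (node in g$nodes) {
    ps <- node_param_shapes(node)
    if (is.null(ps)) next
    if (node$op == "conv") {
      fan_in <- node$k^2 * node$cin / node$groups
      w <- array(stats::rnorm(prod(ps$w), sd = sqrt(2 / fan_in)), dim = ps$w)
      p <- list(w = w)
      if (isTRUE(node$bias)) p$b <- numeric(node$cout)
      g$params[[node$id]] <- p
    } else if (node$op == "bn") {
      g$params[[node$id]] <- list(gamma = rep(1, node$c), beta = rep(0, node$c))
      g$buffers[[node$id]] <- list(rmean = rep(0, node$c), rvar = rep(1, node$c))
    }
  }
  invisible(model)
}

# ---- channel-broadcast helpers ---------------------------------------------

chan_sums <- function(x) {
  d <- dim(x)
  m <- .colSums(x, d[1] * d[2], d[3] * d[4])
  .rowSums(matrix(m, d[3], d[4]), d[3], d[4])
}

chan_bcast <- function(v, d) {
  # v per-channel (length C) -> full (H,W,C,N) vector
  rep(rep(v, each = d[1] * d[2]), times = d[4])
}

cn_bcast <- function(v, d) {
  # v per (channel, image) (length C*N) -> full vector
  rep(v, each = d[1] * d[2])
}

# ---- forward ----------------------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

nn_forward <- function(model, x, training = FALSE) {
  g <- model$graph
  n_nodes <- length(g$nodes)
  acts <- vector("list", n_nodes)
  aux <- vector("list", n_nodes)
  for (node in g$nodes) {
    id <- node$id
    ins <- acts[node$inputs]
    acts[[id]] <- switch(node$op,
      input = x,
      conv = {
        y <- .conv2d_fw(ins[[1]], g$params[[id]]$w, node$stride, node$pad,
                        node$groups)
        if (isTRUE(node$bias)) y <- y + chan_bcast(g$params[[id]]$b, dim(y))
        y
      },
      bn = {
        xx <- ins[[1]]
        d <- dim(xx)
        m <- prod(d[c(1, 2, 4)])
        p <- g$params[[id]]
        if (training) {
          mu <- chan_sums(xx) / m
          xc <- xx - chan_bcast(mu, d)
          v <- chan_sums(xc * xc) / m
          b <- g$buffers[[id]]
          b$rmean <- (1 - BN_MOMENTUM) * b$rmean + BN_MOMENTUM * mu
          b$rvar <- (1 - BN_MOMENTUM) * b$rvar + BN_MOMENTUM * v
          g$buffers[[id]] <- b
          inv <- 1 / sqrt(v + BN_EPS)
          xhat <- xc * chan_bcast(inv, d)
          aux[[id]] <- list(xhat = xhat, inv = inv)
          xhat * chan_bcast(p$gamma, d) + chan_bcast(p$beta, d)
        } else {
          b <- g$buffers[[id]]
          sc <- p$gamma / sqrt(b$rvar + BN_EPS)
          xx * chan_bcast(sc, d) + chan_bcast(p$beta - sc * b$rmean, d)
        }
      },
      relu = pmax(ins[[1]], 0),
      silu = {
        s <- 1 / (1 + exp(-ins[[1]]))
        aux[[id]] <- s
        ins[[1]] * s
      },
      sigmoid = 1 / (1 + exp(-ins[[1]])),
      add = ins[[1]] + ins[[2]],
      concat = {
        d1 <- dim(ins[[1]])
        cs <- vapply(ins, function(a) dim(a)[3], 0)
        y <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
        off <- 0L
        for (a in ins) {
          y[, , off + seq_len(dim(a)[3]), ] <- a
          off <- off + dim(a)[3]
        }
        y
      },
      gap = {
        d <- dim(ins[[1]])
        v <- .colSums(ins[[1]], d[1] * d[2], d[3] * d[4]) / (d[1] * d[2])
        array(v, c(1L, 1L, d[3], d[4]))
      },
      mul_chan = {
        d <- dim(ins[[1]])
        ins[[1]] * cn_bcast(as.vector(ins[[2]]), d)
      },
      up2 = .upsample2_fw(ins[[1]]),
      stop("unknown op: ", node$op)
    )
  }
  structure(list(out = acts[[model$out_id]], acts = acts, aux = aux),
            class = "nn_pass")
}

# ---- backward ---------------------------------------------------------------

# Returns list(grads = per-node param gradients). `pass` must come from a
# training-mode forward.
nn_backward <- function(model, pass, dout) {
  g <- model$graph
  n_nodes <- length(g$nodes)
  dacts <- vector("list", n_nodes)
  grads <- vector("list", n_nodes)
  dacts[[model$out_id]] <- dout
  acc <- function(slot, val) {
    if (is.null(dacts[[slot]])) dacts[[slot]] <<- val
    else dacts[[slot]] <<- dacts[[slot]] + val
  }
  for (id in rev(seq_len(n_nodes))) {
    dy <- dacts[[id]]
    if (is.null(dy)) next
    node <- g$nodes[[id]]
    ins <- pass$acts[node$inputs]
    switch(node$op,
      input = NULL,
      conv = {
        need_dx <- g$nodes[[node$inputs[1]]]$op != "input"
        r <- .conv2d_bw(ins[[1]], g$params[[id]]$w, dy, node$stride, node$pad,
                        node$groups, need_dx)
        grads[[id]] <- list(w = r$dw)
        if (isTRUE(node$bias)) grads[[id]]$b <- chan_sums(dy)
        if (need_dx) acc(node$inputs[1], r$dx)
      },
      bn = {
        a <- pass$aux[[id]]
        d <- dim(dy)
        m <- prod(d[c(1, 2, 4)])
        p <- g$params[[id]]
        dgamma <- chan_sums(dy * a$xhat)
        dbeta <- chan_sums(dy)
        grads[[id]] <- list(gamma = dgamma, beta = dbeta)
        dxhat <- dy * chan_bcast(p$gamma, d)
        s1 <- chan_sums(dxhat)
        s2 <- chan_sums(dxhat * a$xhat)
        dx <- (dxhat - chan_bcast(s1 / m, d) -
                 a$xhat * chan_bcast(s2 / m, d)) * chan_bcast(a$inv, d)
        acc(node$inputs[1], dx)
      },
      relu = acc(node$inputs[1], dy * (ins[[1]] > 0)),
      silu = {
        s <- pass$aux[[id]]
        acc(node$inputs[1], dy * (s * (1 + ins[[1]] * (1 - s))))
      },
      sigmoid = {
        y <- pass$acts[[id]]
        acc(node$inputs[1], dy * y * (1 - y))
      },
      add = {
        acc(node$inputs[1], dy)
        acc(node$inputs[2], dy)
      },
      concat = {
        off <- 0L
        for (k in seq_along(node$inputs)) {
          ck <- dim(ins[[k]])[3]
          acc(node$inputs[k], dy[, , off + seq_len(ck), , drop = FALSE])
          off <- off + ck
        }
      },
      gap = {
        d <- dim(ins[[1]])
        acc(node$inputs[1],
            array(cn_bcast(as.vector(dy) / (d[1] * d[2]), d), d))
      },
      mul_chan = {
        d <- dim(ins[[1]])
        gate <- as.vector(ins[[2]])
        acc(node$inputs[1], dy * cn_bcast(gate, d))
        dg <- .colSums(dy * ins[[1]], d[1] * d[2], d[3] * d[4])
        acc(node$inputs[2], array(dg, dim(ins[[2]])))
      },
      up2 = acc(node$inputs[1], .upsample2_bw(dy)),
      stop("unknown op: ", node$op)
    )
    dacts[[id]] <- NULL  # free as we go
  }
  list(grads = grads)
}

# ---- RNG isolation ----------------------------------------------------------

rng_push <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

rng_pop <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
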