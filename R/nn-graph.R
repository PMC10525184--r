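# Minimal computation-graph engine for small CNNs.
#
# A network is a DAG of named nodes added in topological order. Batches are
# R arrays with dim (C, H, W, N) -- channel fastest -- so per-channel ops
# reduce to matrix(x, nrow = C) arithmetic, and the C++ conv/pool kernels
# share the same layout. Vector-valued nodes (after global pooling /
# flatten) are (features x N) matrices.
#
# Supported ops: input, conv (bias-free), bn, relu, maxpool, add, gap,
# flatten, linear. Each op has a forward that returns (out, cache) and a
# backward that maps the output gradient to input gradient(s) and parameter
# gradients. This explicit reverse pass is also what Grad-CAM taps: the
# gradient of a logit w.r.t. any named node is available by stopping the
# sweep at that node.

net_new <- function(input_shape) {
  structure(list(nodes = list(),
                 shapes = list(input = as.integer(input_shape)),
                 output = NULL),
            class = "tcam_net")
}

net_add <- function(net, name, op, inputs, ...) {
  if (name %in% c("input", names(net$nodes))) stop("duplicate node name: ", name)
  miss <- setdiff(inputs, c("input", names(net$nodes)))
  if (length(miss)) stop("unknown input node(s): ", paste(miss, collapse = ", "))
  cfg <- list(...)
  shape <- op_out_shape(op, net$shapes[inputs], cfg)
  net$nodes[[name]] <- list(name = name, op = op, inputs = inputs, cfg = cfg)
  net$shapes[[name]] <- shape
  net$output <- name
  net
}

op_out_shape <- function(op, in_shapes, cfg) {
  s <- in_shapes[[1L]]
  switch(op,
    conv = {
      oh <- (s[2L] + 2L * cfg$pad[1L] - cfg$kernel[1L]) %/% cfg$stride[1L] + 1L
      ow <- (s[3L] + 2L * cfg$pad[2L] - cfg$kernel[2L]) %/% cfg$stride[2L] + 1L
      if (oh < 1L || ow < 1L) stop("conv output collapses to zero size")
      c(cfg$filters, oh, ow)
    },
    maxpool = {
      oh <- (s[2L] + 2L * cfg$pad[1L] - cfg$kernel[1L]) %/% cfg$stride[1L] + 1L
      ow <- (s[3L] + 2L * cfg$pad[2L] - cfg$kernel[2L]) %/% cfg$stride[2L] + 1L
      c(s[1L], oh, ow)
    },
    bn = s,
    relu = s,
    add = {
      if (!identical(in_shapes[[1L]], in_shapes[[2L]]))
        stop("add: input shapes differ")
      s
    },
    gap = s[1L],
    flatten = prod(s),
    linear = cfg$units,
    stop("unknown op: ", op)
  )
}

# Parameter / batch-norm state initialisation. Convolution and linear
# weights use He-normal init (fresh layers of a ReLU network); batch norm
# starts at identity with zeroed running mean, unit running variance.
net_init_params <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  params <- list()
  state <- list()
  for (nd in net$nodes) {
    s_in <- net$shapes[[nd$inputs[1L]]]
    if (nd$op == "conv") {
      k <- nd$cfg$kernel
      fan_in <- s_in[1L] * k[1L] * k[2L]
      params[[nd$name]] <- list(
        w = array(rnorm(fan_in * nd$cfg$filters, sd = sqrt(2 / fan_in)),
                  dim = c(s_in[1L], k[1L], k[2L], nd$cfg$filters)))
    } else if (nd$op == "bn") {
      C <- s_in[1L]
      params[[nd$name]] <- list(gamma = rep(1, C), beta = rep(0, C))
      state[[nd$name]] <- list(rm = rep(0, C), rv = rep(1, C))
    } else if (nd$op == "linear") {
      fan_in <- s_in[1L]
      params[[nd$name]] <- list(
        w = matrix(rnorm(nd$cfg$units * fan_in, sd = sqrt(2 / fan_in)),
                   nrow = nd$cfg$units),
        b = rep(0, nd$cfg$units))
    }
  }
  list(params = params, state = state)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

net_forward <- function(net, params, state, x, training = FALSE,
                        keep_cache = FALSE) {
  vals <- list(input = x)
  caches <- if (keep_cache) list() else NULL
  for (nd in net$nodes) {
    a <- vals[[nd$inputs[1L]]]
    res <- switch(nd$op,
      conv = {
        out <- cpp_conv2d_fwd(a, params[[nd$name]]$w,
                              nd$cfg$stride[1L], nd$cfg$stride[2L],
                              nd$cfg$pad[1L], nd$cfg$pad[2L])
        list(out = out, cache = if (keep_cache) list(x = a))
      },
      bn = {
        p <- params[[nd$name]]; st <- state[[nd$name]]
        C <- dim(a)[1L]
        m2 <- matrix(a, nrow = C)
        if (training) {
          mu <- rowMeans(m2)
          xc <- m2 - mu
          v <- rowMeans(xc * xc)
          inv <- 1 / sqrt(v + BN_EPS)
          xhat <- xc * inv
          M <- ncol(m2)
          ub <- if (M > 1L) M / (M - 1) else 1
          state[[nd$name]] <- list(
            rm = (1 - BN_MOMENTUM) * st$rm + BN_MOMENTUM * mu,
            rv = (1 - BN_MOMENTUM) * st$rv + BN_MOMENTUM * v * ub)
        } else {
          inv <- 1 / sqrt(st$rv + BN_EPS)
          xhat <- (m2 - st$rm) * inv
        }
        out <- array(p$gamma * xhat + p$beta, dim = dim(a))
        list(out = out,
             cache = if (keep_cache) list(xhat = xhat, inv = inv,
                                          dims = dim(a), training = training))
      },
      relu = {
        out <- a
        out[out < 0] <- 0
        list(out = out, cache = if (keep_cache) list(mask = a > 0))
      },
      maxpool = {
        mp <- cpp_maxpool_fwd(a, nd$cfg$kernel[1L], nd$cfg$kernel[2L],
                              nd$cfg$stride[1L], nd$cfg$stride[2L],
                              nd$cfg$pad[1L], nd$cfg$pad[2L])
        list(out = mp$out,
             cache = if (keep_cache) list(idx = mp$idx, xdim = dim(a)))
      },
      add = {
        b <- vals[[nd$inputs[2L]]]
        list(out = a + b, cache = NULL)
      },
      gap = {
        d <- dim(a)
        hw <- d[2L] * d[3L]
        m2 <- array(a, dim = c(d[1L], hw, d[4L]))
        out <- vapply(seq_len(d[4L]),
                      function(n) rowMeans(matrix(m2[, , n], nrow = d[1L])),
                      numeric(d[1L]))
        out <- matrix(out, nrow = d[1L])
        list(out = out, cache = if (keep_cache) list(dims = d))
      },
      flatten = {
        d <- dim(a)
        list(out = matrix(a, ncol = d[4L]),
             cache = if (keep_cache) list(dims = d))
      },
      linear = {
        p <- params[[nd$name]]
        list(out = p$w %*% a + p$b, cache = if (keep_cache) list(x = a))
      },
      stop("unknown op: ", nd$op))
    vals[[nd$name]] <- res$out
    if (keep_cache) caches[[nd$name]] <- res$cache
  }
  list(values = vals, caches = caches, state = state,
       logits = vals[[net$output]])
}

# Reverse sweep. dlogits is the gradient at the output node. If `upto` is a
# node name, the sweep stops there and returns the fully-accumulated
# gradient of the scalar objective w.r.t. that node's output (used by
# Grad-CAM). Otherwise returns parameter gradients.
net_backward <- function(net, params, caches, values, dlogits, upto = NULL) {
  gout <- list()
  gout[[net$output]] <- dlogits
  pgrads <- list()
  for (nd in rev(net$nodes)) {
    g <- gout[[nd$name]]
    if (is.null(g)) next
    if (!is.null(upto) && nd$name == upto)
      return(list(d_at = g, pgrads = pgrads))
    cache <- caches[[nd$name]]
    dins <- switch(nd$op,
      conv = {
        bw <- cpp_conv2d_bwd(cache$x, params[[nd$name]]$w, g,
                             nd$cfg$stride[1L], nd$cfg$stride[2L],
                             nd$cfg$pad[1L], nd$cfg$pad[2L])
        pgrads[[nd$name]] <- list(w = bw$dw)
        list(bw$dx)
      },
      bn = {
        C <- cache$dims[1L]
        dm <- matrix(g, nrow = C)
        dgamma <- rowSums(dm * cache$xhat)
        dbeta <- rowSums(dm)
        pgrads[[nd$name]] <- list(gamma = dgamma, beta = dbeta)
        dxhat <- dm * params[[nd$name]]$gamma
        # in eval mode the normalisation constants do not depend on x,
        # so the mean-subtraction terms of the training-mode formula vanish
        dx <- if (isTRUE(cache$training))
          cache$inv * (dxhat - rowMeans(dxhat) -
                         cache$xhat * rowMeans(dxhat * cache$xhat))
        else cache$inv * dxhat
        list(array(dx, dim = cache$dims))
      },
      relu = {
        dx <- g
        dx[!cache$mask] <- 0
        list(dx)
      },
      maxpool = list(cpp_maxpool_bwd(g, cache$idx, cache$xdim)),
      add = list(g, g),
      gap = {
        d <- cache$dims
        hw <- d[2L] * d[3L]
        list(array(g[, rep(seq_len(d[4L]), each = hw), drop = FALSE] / hw,
                   dim = d))
      },
      flatten = list(array(g, dim = cache$dims)),
      linear = {
        p <- params[[nd$name]]
        pgrads[[nd$name]] <- list(w = g %*% t(cache$x), b = rowSums(g))
        list(t(p$w) %*% g)
      },
      stop("unknown op: ", nd$op))
    for (i in seq_along(nd$inputs)) {
      nm <- nd$inputs[i]
      gout[[nm]] <- if (is.null(gout[[nm]])) dins[[i]] else gout[[nm]] + dins[[i]]
    }
    gout[[nd$name]] <- NULL  # free
  }
  list(d_at = gout[["input"]], pgrads = pgrads)
}

# Numerically stable softmax cross-entropy over a (C x N) logit matrix with
# 1-based integer labels. Returns loss, gradient w.r.t. logits, and
# probabilities.
softmax_ce <- function(logits, labels) {
  n <- ncol(logits)
  z <- logits - rep(apply(logits, 2L, max), each = nrow(logits))
  e <- exp(z)
  p <- e / rep(colSums(e), each = nrow(logits))
  ix <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[ix], 1e-300)))
  dl <- p
  dl[ix] <- dl[ix] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}
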