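# Minimal reverse-mode differentiation engine.
#
# Values are dense arrays; convolutional feature maps use the layout
# [C, H, W, N] (channel fastest) so that im2col + one BLAS GEMM performs a
# convolution without any post-hoc permutation.  Each forward op appends a
# node to a tape; backward() walks the tape in reverse, accumulating
# gradients into parameter nodes.  Deliberately small: only the ops the
# architectures in this package need.

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

tape_push <- function(tape, node) {
  if (is.null(tape)) return(invisible(node))
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- node
  tape$n <- n
  invisible(node)
}

# A node is an environment: val, grad (NULL until touched), bw (closure adding
# into parents' grads), requires_grad.  Parameters are nodes with no tape.
ag_node <- function(val, tape = NULL, bw = NULL, requires_grad = !is.null(bw)) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- bw
  nd$requires_grad <- requires_grad
  tape_push(tape, nd)
  nd
}

ag_param <- function(val) {
  nd <- ag_node(val, requires_grad = TRUE)
  nd$is_param <- TRUE
  nd
}

ag_const <- function(val) ag_node(val, requires_grad = FALSE)

ag_accum <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

ag_backward <- function(loss, tape) {
  loss$grad <- 1
  if (tape$n == 0L) return(invisible(NULL))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
    if (is.null(nd$is_param)) nd$grad <- NULL  # free intermediate grads
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Temporarily mark parameters (non-)trainable.  Backward closures consult
# requires_grad and skip the expensive weight-gradient GEMMs of frozen
# networks entirely; input gradients still flow through them.
params_set_trainable <- function(params, trainable) {
  for (p in params) p$requires_grad <- trainable
  invisible(NULL)
}

# ---- elementwise ops --------------------------------------------------------

ag_add <- function(a, b, tape) {
  ag_node(a$val + b$val, tape, bw = function(g) {
    ag_accum(a, g); ag_accum(b, g)
  })
}

ag_mul <- function(a, b, tape) {
  ag_node(a$val * b$val, tape, bw = function(g) {
    ag_accum(a, g * b$val); ag_accum(b, g * a$val)
  })
}

ag_sigmoid <- function(x, tape) {
  s <- 1 / (1 + exp(-x$val))
  ag_node(s, tape, bw = function(g) ag_accum(x, g * s * (1 - s)))
}

ag_tanh <- function(x, tape) {
  s <- tanh(x$val)
  ag_node(s, tape, bw = function(g) ag_accum(x, g * (1 - s * s)))
}

ag_relu <- function(x, tape) {
  m <- x$val > 0
  ag_node(x$val * m, tape, bw = function(g) ag_accum(x, g * m))
}

ag_lrelu <- function(x, slope, tape) {
  fac <- slope + (1 - slope) * (x$val > 0)
  ag_node(x$val * fac, tape,
          bw = function(g) ag_accum(x, g * fac))
}

ag_clamp01 <- function(x, tape) {
  inside <- x$val > 0 & x$val < 1
  ag_node(pmin(pmax(x$val, 0), 1), tape,
          bw = function(g) ag_accum(x, g * inside))
}

ag_dropout <- function(x, p, training, tape) {
  if (!training || p <= 0) return(x)
  mask <- (array(stats::runif(length(x$val)), dim = dim(x$val) %||% length(x$val)) >= p) / (1 - p)
  ag_node(x$val * mask, tape, bw = function(g) ag_accum(x, g * mask))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- shape ops --------------------------------------------------------------

ag_reshape <- function(x, new_dim, tape) {
  od <- dim(x$val)
  v <- x$val
  dim(v) <- new_dim
  ag_node(v, tape, bw = function(g) {
    dim(g) <- od
    ag_accum(x, g)
  })
}

# concatenate along the channel (first) dimension of [C,H,W,N] arrays,
# or the row dimension of matrices
ag_concat_c <- function(xs, tape) {
  dims <- lapply(xs, function(x) dim(x$val))
  nd_len <- length(dims[[1]])
  cs <- vapply(dims, `[`, 0, 1L)
  offsets <- cumsum(c(0, cs))
  if (nd_len == 2) {
    val <- do.call(rbind, lapply(xs, function(x) x$val))
  } else {
    rest <- dims[[1]][-1]
    val <- array(0, dim = c(sum(cs), rest))
    m <- matrix(val, nrow = sum(cs))
    for (i in seq_along(xs)) {
      m[(offsets[i] + 1):offsets[i + 1], ] <- matrix(xs[[i]]$val, nrow = cs[i])
    }
    val <- array(m, dim = c(sum(cs), rest))
  }
  ag_node(val, tape, bw = function(g) {
    gm <- matrix(g, nrow = sum(cs))
    for (i in seq_along(xs)) {
      gi <- gm[(offsets[i] + 1):offsets[i + 1], , drop = FALSE]
      dim(gi) <- dims[[i]]
      ag_accum(xs[[i]], gi)
    }
  })
}

ag_slice_c <- function(x, from, to, tape) {
  d <- dim(x$val)
  v <- if (length(d) == 4) x$val[from:to, , , , drop = FALSE]
       else x$val[from:to, , drop = FALSE]
  ag_node(v, tape, bw = function(g) {
    full <- array(0, dim = d)
    if (length(d) == 4) full[from:to, , , ] <- g else full[from:to, ] <- g
    ag_accum(x, full)
  })
}

# broadcast a parameter of shape [.., 1] along the batch dimension (last)
ag_bcast_n <- function(x, n, tape) {
  d <- dim(x$val)
  v <- array(rep(as.vector(x$val), n), dim = c(d[-length(d)], n))
  ag_node(v, tape, bw = function(g) {
    gm <- matrix(g, ncol = n)
    gs <- rowSums(gm)
    dim(gs) <- d
    ag_accum(x, gs)
  })
}

# ---- dense / convolutional ops ---------------------------------------------

# x: [F, N] matrix; w: [F, U]; b: length U
ag_fc <- function(x, w, b, tape) {
  y <- crossprod(w$val, x$val) + b$val
  ag_node(y, tape, bw = function(g) {
    if (w$requires_grad) {
      ag_accum(w, tcrossprod(x$val, g))
      ag_accum(b, rowSums(g))
    }
    if (x$requires_grad) ag_accum(x, w$val %*% g)
  })
}

# x: [C,H,W,N]; w: [Cin,kh,kw,Cout]; b: length Cout
ag_conv2d <- function(x, w, b, stride, pad, tape) {
  d <- dim(x$val)
  wd <- dim(w$val)
  kh <- wd[2]; kw <- wd[3]; cout <- wd[4]
  wm <- matrix(w$val, nrow = prod(wd[1:3]), ncol = cout)
  y <- cpp_conv_fw(x$val, wm, b$val, d[1], d[2], d[3], d[4],
                   kh, kw, stride, pad)
  ag_node(y, tape, bw = function(g) {
    r <- cpp_conv_bw(x$val, wm, g, d[1], d[2], d[3], d[4],
                     kh, kw, stride, pad, x$requires_grad, w$requires_grad)
    if (w$requires_grad) {
      dw <- r$dw
      dim(dw) <- wd
      ag_accum(w, dw)
      ag_accum(b, r$db)
    }
    if (x$requires_grad) {
      dx <- r$dx
      dim(dx) <- d
      ag_accum(x, dx)
    }
  })
}

# transposed convolution: the adjoint of ag_conv2d's linear map.
# x: [Cin,h,w,N]; w: [Cout,kh,kw,Cin] (note: stored with the *output*
# channels first so that the same im2col row convention applies);
# output size (h-1)*stride - 2*pad + kh + output_padding
ag_conv_transpose2d <- function(x, w, b, stride, pad, output_padding, tape) {
  d <- dim(x$val)
  wd <- dim(w$val)
  cout <- wd[1]; kh <- wd[2]; kw <- wd[3]; cin <- wd[4]
  stopifnot(cin == d[1])
  wm <- matrix(w$val, nrow = prod(wd[1:3]), ncol = cin)
  y <- cpp_convT_fw(x$val, wm, b$val, d[1], d[2], d[3], d[4], cout,
                    kh, kw, stride, pad, output_padding)
  ag_node(y, tape, bw = function(g) {
    r <- cpp_convT_bw(x$val, wm, g, d[1], d[2], d[3], d[4], cout,
                      kh, kw, stride, pad, output_padding, x$requires_grad,
                      w$requires_grad)
    if (w$requires_grad) {
      dw <- r$dw
      dim(dw) <- wd
      ag_accum(w, dw)
      ag_accum(b, r$db)
    }
    if (x$requires_grad) {
      dx <- r$dx
      dim(dx) <- d
      ag_accum(x, dx)
    }
  })
}

ag_maxpool2 <- function(x, tape) {
  d <- dim(x$val)
  r <- cpp_maxpool2_fw(x$val, d[1], d[2], d[3], d[4])
  y <- r$y
  dim(y) <- c(d[1], d[2] %/% 2L, d[3] %/% 2L, d[4])
  idx <- r$idx
  n_in <- length(x$val)
  ag_node(y, tape, bw = function(g) {
    dx <- cpp_maxpool2_bw(g, idx, n_in)
    dim(dx) <- d
    ag_accum(x, dx)
  })
}

# nearest-neighbour upsampling to an arbitrary target size (feedback paths
# must undo pooling even when the pooled size was rounded down)
ag_upsample_nn <- function(x, oh, ow, tape) {
  d <- dim(x$val)
  ih <- pmin(d[2], floor(seq_len(oh) * d[2] / oh - d[2] / (2 * oh)) + 1L)
  iw <- pmin(d[3], floor(seq_len(ow) * d[3] / ow - d[3] / (2 * ow)) + 1L)
  ih <- pmax(ih, 1L); iw <- pmax(iw, 1L)
  v <- x$val[, ih, iw, , drop = FALSE]
  ag_node(v, tape, bw = function(g) {
    dx <- array(0, dim = d)
    for (j in seq_len(ow)) {
      for (i in seq_len(oh)) {
        dx[, ih[i], iw[j], ] <- dx[, ih[i], iw[j], ] + g[, i, j, ]
      }
    }
    ag_accum(x, dx)
  })
}

# ---- batch normalization ----------------------------------------------------

# Normalizes over all dims but the first (channel/unit).  `state` is an
# environment holding running_mean / running_var for evaluation mode.
ag_batchnorm <- function(x, gamma, beta, state, training, tape, momentum = 0.1,
                         eps = 1e-5) {
  d <- dim(x$val) %||% c(length(x$val), 1L)
  C <- d[1]
  m <- matrix(x$val, nrow = C)
  nobs <- ncol(m)
  if (training) {
    mu <- rowMeans(m)
    xc <- m - mu
    va <- rowMeans(xc * xc)
    if (is.null(state$running_mean)) {
      state$running_mean <- mu
      state$running_var <- va
    } else {
      state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
      state$running_var <- (1 - momentum) * state$running_var + momentum * va
    }
  } else {
    mu <- state$running_mean %||% rep(0, C)
    va <- state$running_var %||% rep(1, C)
    xc <- m - mu
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  y <- xhat * gamma$val + beta$val
  dim(y) <- d
  ag_node(y, tape, bw = function(g) {
    gm <- matrix(g, nrow = C)
    if (gamma$requires_grad) {
      ag_accum(gamma, rowSums(gm * xhat))
      ag_accum(beta, rowSums(gm))
    }
    if (!x$requires_grad) return(invisible(NULL))
    gxhat <- gm * gamma$val
    if (training) {
      dx <- istd * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    } else {
      dx <- istd * gxhat
    }
    dim(dx) <- d
    ag_accum(x, dx)
  })
}

# ---- losses -----------------------------------------------------------------

# logits: [K, N]; labels: integer vector in 1..K.  Mean cross-entropy.
ag_softmax_ce <- function(logits, labels, tape) {
  z <- logits$val
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  ez <- exp(z)
  p <- ez / matrix(colSums(ez), nrow(z), ncol(z), byrow = TRUE)
  n <- ncol(z)
  picked <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  ag_node(loss, tape, bw = function(g) {
    d <- p
    d[cbind(labels, seq_len(n))] <- d[cbind(labels, seq_len(n))] - 1
    ag_accum(logits, g * d / n)
  })
}

# binary cross-entropy on logits (numerically stable); target in [0,1]
ag_bce_logits <- function(logits, target, tape) {
  z <- logits$val
  t <- if (is.numeric(target)) target else target$val
  loss <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  n <- length(z)
  ag_node(loss, tape, bw = function(g) {
    p <- 1 / (1 + exp(-z))
    ag_accum(logits, g * (p - t) / n)
  })
}

ag_mse <- function(pred, target, tape) {
  t <- if (is.numeric(target)) target else target$val
  d <- pred$val - t
  n <- length(d)
  ag_node(mean(d * d), tape, bw = function(g) ag_accum(pred, g * 2 * d / n))
}

ag_scalar_sum <- function(xs, weights = NULL, tape = NULL) {
  w <- weights %||% rep(1, length(xs))
  val <- sum(vapply(seq_along(xs), function(i) w[i] * xs[[i]]$val, 0))
  ag_node(val, tape, bw = function(g) {
    for (i in seq_along(xs)) ag_accum(xs[[i]], g * w[i])
  })
}

# fused (Conv)LSTM cell: z holds stacked gate pre-activations [4C, ...],
# c_prev the previous cell state [C, ...].  Returns h and c nodes.  The
# backward pass is deferred to an anchor node created *before* h and c on
# the tape, so that it runs only after both downstream gradients arrived.
ag_lstm_cell <- function(z, c_prev, tape) {
  d <- dim(z$val)
  C <- d[1] %/% 4L
  R <- as.integer(prod(d[-1]))
  fw <- cpp_lstm_cell_fw(z$val, c_prev$val, C, R)
  hd <- c(C, d[-1])
  cell <- new.env(parent = emptyenv())
  anchor <- ag_node(0, tape, bw = NULL, requires_grad = TRUE)
  hnode <- ag_node(array(fw$h, hd), tape, bw = function(g) cell$gh <- g,
                   requires_grad = TRUE)
  cnode <- ag_node(array(fw$c, hd), tape, bw = function(g) cell$gc <- g,
                   requires_grad = TRUE)
  anchor$grad <- 0
  anchor$bw <- function(g) {
    if (is.null(cell$gh) && is.null(cell$gc)) return(invisible(NULL))
    r <- cpp_lstm_cell_bw(
      cell$gh %||% numeric(0), cell$gc %||% numeric(0),
      fw$gates, c_prev$val, fw$c, C, R)
    dz <- r$dz; dim(dz) <- d
    ag_accum(z, dz)
    dc <- r$dc_prev; dim(dc) <- hd
    ag_accum(c_prev, dc)
  }
  list(h = hnode, c = cnode)
}

# ---- optimizer --------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

# params: named list of ag_param nodes.  Standard Adam; l2 is coupled weight
# decay added to the raw gradient (classical L2, not decoupled).
adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      l2 = 0) {
  st$t <- (st$t %||% 0L) + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    if (l2 > 0) g <- g + l2 * p$val
    key_m <- paste0(nm, ".m"); key_v <- paste0(nm, ".v")
    m <- (st[[key_m]] %||% 0) * beta1 + (1 - beta1) * g
    v <- (st[[key_v]] %||% 0) * beta2 + (1 - beta2) * g * g
    st[[key_m]] <- m
    st[[key_v]] <- v
    p$val <- p$val - lr * (m / b1t) / (sqrt(v / b2t) + eps)
  }
  invisible(NULL)
}
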